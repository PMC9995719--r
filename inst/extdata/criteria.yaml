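# Centre/patient eligibility thresholds and follow-up traffic lights.
# Boundary conventions: volume thresholds are inclusive (>= 10 allo,
# >= 5 auto per year on average); the reporting gate and the follow-up
# outcome gate are strict (> 0.80); traffic lights are green > 0.90,
# red < 0.80, amber otherwise.
version: 1
min_annual_volume:
  allogeneic: 10
  autologous: 5
reporting_gate: 0.80
followup_gate: 0.80
traffic_light:
  green_above: 0.90
  red_below: 0.80
adult_age: 18
horizon_days: 365
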