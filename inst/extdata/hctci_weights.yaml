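# HCT-CI comorbidity weights (Sorror-style defaults, 17 categories).
# Editable: the index is shipped as data so a registry can review or
# override the weighting without touching code.
version: 1
weights:
  arrhythmia: 1
  cardiac: 1
  inflammatory_bowel_disease: 1
  diabetes: 1
  cerebrovascular_disease: 1
  psychiatric_disturbance: 1
  hepatic_mild: 1
  obesity: 1
  infection: 1
  rheumatologic: 2
  peptic_ulcer: 2
  renal_moderate_severe: 2
  pulmonary_moderate: 2
  prior_solid_tumor: 3
  heart_valve_disease: 3
  pulmonary_severe: 3
  hepatic_moderate_severe: 3
bands:
  low: [0, 0]
  intermediate: [1, 2]
  high: [3, .inf]
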