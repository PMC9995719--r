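# Case-mix model and imputation specification.
# Covariates are names of columns produced by casemix_frame(); the list
# is editable and echoed into the run manifest for auditability.
version: 1
covariates:
  - age_decade
  - dri_overall
  - hctci_band
  - perf10
imputation:
  m: 5
  iterations: 10
funnel:
  alpha: 0.05
  adjust: bonferroni
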