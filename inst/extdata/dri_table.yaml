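# Adapted Disease Risk Index lookup, shipped as reviewable data.
#
# Adaptations relative to the original index:
#   * MDS other than RAEB-1, RAEB-2 or transformed-to-AML is low-risk MDS
#     (disease group "low") and does not require cytogenetics.
#   * AML cytogenetic risk follows the UK MRC grouping; MDS (RAEB-1/2 or
#     transformed) follows the original MDS categorization.
#   * Cytogenetics count as missing when no chromosome analysis result is
#     registered or the result is "abnormal, no further details".
#   * Five diagnostic groups absent from the original index (bone marrow
#     failure, inherited disorders, autoimmune diseases, histiocytic
#     disorders, hemoglobinopathies) are classified overall low risk.
#   * A record whose cytogenetics or stage is missing where required is
#     imputed overall "intermediate" and flagged.
version: 1
low_risk_diagnoses:
  - bone_marrow_failure
  - inherited_disorder
  - autoimmune
  - histiocytic
  - hemoglobinopathy
aml_by_cytogenetics:
  favorable: low
  intermediate: intermediate
  adverse: high
# MDS with substage RAEB1 / RAEB2 / transformed_AML:
mds_highrisk_by_cytogenetics:
  favorable: intermediate
  intermediate: intermediate
  adverse: high
mds_lowrisk_group: low
disease_groups:
  ALL: intermediate
  lymphoma: intermediate
  myeloma: intermediate
  other_haem: intermediate
  solid_tumor: high
  non_haem: high
stage_groups:
  early: early
  intermediate: early
  advanced: advanced
overall:
  low:
    early: low
    advanced: intermediate
  intermediate:
    early: intermediate
    advanced: high
  high:
    early: high
    advanced: very_high
imputed_overall: intermediate
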