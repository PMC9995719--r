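# Fixtures built in code: a record constructor with sensible defaults,
# a fully-observed simulation configuration, and the hand-constructed
# scoring vignette table shared by the risk-score and acceptance tests.

test_window <- function() {
  analysis_window("2015-01-01", "2019-12-31", "2021-05-14")
}

# One-call patient constructor; any field can be overridden (recycled to n).
make_patients <- function(n = 1, ...) {
  base <- list(
    patient_id = sprintf("P%03d", seq_len(n)),
    center_code = "C1", transplant_type = "allogeneic",
    transplant_number = 1L, transplant_date = as.Date("2016-06-15"),
    diagnosis = "AML", disease_stage = "early",
    mds_substage = NA_character_,
    cytogenetics_status = "abnormal_classified",
    cytogenetics_risk = "intermediate",
    age_years = 50, sex = "M", performance_score = 90L,
    donor_type = "MSD", graft_source = "PB",
    conditioning_intensity = "MAC",
    comorbidity_any = "no", comorbidities = "",
    n_molecular_markers = 0L,
    last_contact_days = 365L, vital_status = "alive",
    death_days = NA_integer_)
  override <- list(...)
  base[names(override)] <- override
  out <- data.frame(lapply(base, rep_len, length.out = n),
                    stringsAsFactors = FALSE)
  out$transplant_date <- as.Date(out$transplant_date)
  out
}

# Simulation configuration with every source of missingness switched off
# (cytogenetics always classified), so DRI and HCT-CI are complete.
complete_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(
    missingness = list(comorbidity = c(0, 0), cytogenetics = c(0, 0),
                       stage = c(0, 0), performance = c(0, 0),
                       severity_boost = 1, center_range = 0),
    covariate_model = list(cyto_status = c(normal = 0.5,
                                           abnormal_classified = 0.5,
                                           abnormal_no_detail = 0,
                                           not_done = 0)))
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# Hand-constructed scoring cases exercising every special rule of the two
# composite indices. Expected values are hand-derived from the shipped
# weight and lookup tables.
scoring_cases <- function() {
  w <- hctci_weights()
  cases <- list()
  add <- function(patient, expect) {
    cases[[length(cases) + 1]] <<- list(patient = patient, expect = expect)
  }
  # --- HCT-CI ---
  add(make_patients(comorbidity_any = "no"),
      list(hctci_score = 0L, hctci_band = "low",
           hctci_derivation = "complete"))
  add(make_patients(comorbidity_any = "yes",
                    comorbidities = "pulmonary_severe;diabetes"),
      list(hctci_score = 4L, hctci_band = "high",
           hctci_derivation = "partial_assumed_absent"))
  add(make_patients(comorbidity_any = "yes", comorbidities = ""),
      list(hctci_derivation = "missing"))
  add(make_patients(comorbidity_any = NA_character_, comorbidities = ""),
      list(hctci_derivation = "missing"))
  add(make_patients(comorbidity_any = "yes",
                    comorbidities = paste(names(w), collapse = ";")),
      list(hctci_score = as.integer(sum(w)), hctci_band = "high"))
  add(make_patients(comorbidity_any = "yes", comorbidities = "peptic_ulcer"),
      list(hctci_score = 2L, hctci_band = "intermediate"))
  add(make_patients(comorbidity_any = "yes", comorbidities = "diabetes"),
      list(hctci_score = 1L, hctci_band = "intermediate"))
  # --- DRI: extra low-risk diagnostic groups ---
  for (dx in c("bone_marrow_failure", "inherited_disorder", "autoimmune",
               "histiocytic", "hemoglobinopathy")) {
    add(make_patients(diagnosis = dx, disease_stage = NA_character_,
                      cytogenetics_status = NA_character_,
                      cytogenetics_risk = NA_character_),
        list(dri_overall = "low", dri_imputed = FALSE,
             dri_missing_reason = "none"))
  }
  # --- DRI: AML cytogenetics rules ---
  add(make_patients(diagnosis = "AML",
                    cytogenetics_status = "abnormal_no_detail",
                    cytogenetics_risk = NA_character_),
      list(dri_overall = "intermediate", dri_imputed = TRUE,
           dri_missing_reason = "cytogenetics"))
  add(make_patients(diagnosis = "AML", cytogenetics_status = "not_done",
                    cytogenetics_risk = NA_character_),
      list(dri_overall = "intermediate", dri_imputed = TRUE,
           dri_missing_reason = "cytogenetics"))
  add(make_patients(diagnosis = "AML", cytogenetics_risk = "favorable",
                    disease_stage = "early"),
      list(dri_overall = "low", dri_imputed = FALSE))
  add(make_patients(diagnosis = "AML", cytogenetics_risk = "adverse",
                    disease_stage = "advanced"),
      list(dri_overall = "very_high", dri_imputed = FALSE))
  add(make_patients(diagnosis = "AML", cytogenetics_risk = "intermediate",
                    disease_stage = "early"),
      list(dri_overall = "intermediate"))
  add(make_patients(diagnosis = "AML", cytogenetics_risk = "favorable",
                    disease_stage = NA_character_),
      list(dri_overall = "intermediate", dri_imputed = TRUE,
           dri_missing_reason = "stage"))
  add(make_patients(diagnosis = "AML",
                    cytogenetics_status = "abnormal_no_detail",
                    cytogenetics_risk = NA_character_,
                    disease_stage = NA_character_),
      list(dri_overall = "intermediate", dri_imputed = TRUE,
           dri_missing_reason = "both"))
  # --- DRI: MDS substage rules ---
  add(make_patients(diagnosis = "MDS", mds_substage = "other",
                    cytogenetics_status = "not_done",
                    cytogenetics_risk = NA_character_,
                    disease_stage = "early"),
      list(dri_overall = "low", dri_imputed = FALSE,
           dri_disease_group = "low"))
  add(make_patients(diagnosis = "MDS", mds_substage = "RAEB2",
                    cytogenetics_risk = "adverse",
                    disease_stage = "advanced"),
      list(dri_overall = "very_high", dri_disease_group = "high"))
  add(make_patients(diagnosis = "MDS", mds_substage = "RAEB1",
                    cytogenetics_status = "not_done",
                    cytogenetics_risk = NA_character_),
      list(dri_overall = "intermediate", dri_imputed = TRUE,
           dri_missing_reason = "cytogenetics"))
  add(make_patients(diagnosis = "MDS", mds_substage = "transformed_AML",
                    cytogenetics_risk = "intermediate",
                    disease_stage = "early"),
      list(dri_overall = "intermediate", dri_imputed = FALSE))
  # --- DRI: lookup table corners ---
  add(make_patients(diagnosis = "lymphoma", disease_stage = "early",
                    cytogenetics_status = NA_character_,
                    cytogenetics_risk = NA_character_),
      list(dri_overall = "intermediate"))
  add(make_patients(diagnosis = "lymphoma", disease_stage = "advanced",
                    cytogenetics_status = NA_character_,
                    cytogenetics_risk = NA_character_),
      list(dri_overall = "high"))
  add(make_patients(diagnosis = "myeloma", disease_stage = "intermediate",
                    transplant_type = "autologous", donor_type = "auto",
                    cytogenetics_status = NA_character_,
                    cytogenetics_risk = NA_character_),
      list(dri_overall = "intermediate", dri_stage_group = "early"))
  cases
}

# Centre fixture for the volume/reporting criteria: n first transplants of
# one type at one centre over the window, plus matching activity rows.
volume_fixture <- function(n, type = "allogeneic", center = "V1",
                           survey_total = n, window = test_window()) {
  pts <- make_patients(n, center_code = center, transplant_type = type,
                       donor_type = if (type == "autologous") "auto" else "MSD",
                       diagnosis = if (type == "autologous") "myeloma" else "AML",
                       age_years = 50,
                       transplant_date = window$start + (seq_len(n) %% 1500))
  yrs <- seq(as.integer(format(window$start, "%Y")),
             as.integer(format(window$end, "%Y")))
  per <- diff(round(seq(0, survey_total, length.out = length(yrs) + 1)))
  act <- data.frame(center_code = center, year = yrs, transplant_type = type,
                    transplants_survey = per, full_member = TRUE,
                    stringsAsFactors = FALSE)
  list(patients = pts, activity = act)
}
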