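# HCT-CI and adapted DRI scoring: the hand-constructed rule table,
# error paths, monotonicity and invariance properties.

test_that("every hand-constructed scoring case reproduces the rule table", {
  cases <- scoring_cases()
  expect_gte(length(cases), 20)
  for (case in cases) {
    got <- cbind(score_hct_ci(case$patient), score_dri(case$patient))
    for (field in names(case$expect)) {
      expect_equal(got[[field]][1], case$expect[[field]],
                   label = sprintf("%s for case '%s'", field,
                                   case$patient$patient_id[1]))
    }
  }
})

test_that("unknown labels abort with the offending name", {
  expect_error(score_hct_ci(make_patients(comorbidity_any = "yes",
                                          comorbidities = "gout")),
               "gout")
  p <- make_patients(diagnosis = "AML")
  p$diagnosis <- "dragonpox"
  expect_error(score_dri(p), "dragonpox")
})

test_that("adding a comorbidity never decreases the HCT-CI score", {
  w <- hctci_weights()
  set.seed(1)
  for (i in 1:40) {
    s <- sample(names(w), sample(0:8, 1))
    extra <- sample(setdiff(names(w), s), 1)
    p1 <- make_patients(comorbidity_any = "yes",
                        comorbidities = paste(s, collapse = ";"))
    p2 <- make_patients(comorbidity_any = "yes",
                        comorbidities = paste(c(s, extra), collapse = ";"))
    s1 <- score_hct_ci(p1)$hctci_score
    s2 <- score_hct_ci(p2)$hctci_score
    if (length(s) == 0) s1 <- 0L  # empty set scores as missing
    expect_gte(s2, s1)
  }
})

test_that("DRI depends only on diagnosis, stage and cytogenetics", {
  base <- make_patients(diagnosis = "AML", cytogenetics_risk = "adverse",
                        disease_stage = "early")
  tweaked <- make_patients(diagnosis = "AML", cytogenetics_risk = "adverse",
                           disease_stage = "early",
                           age_years = 7, donor_type = "cord",
                           graft_source = "CB",
                           conditioning_intensity = "RIC", sex = "F",
                           transplant_type = "autologous")
  expect_equal(score_dri(base)[-1], score_dri(tweaked)[-1])
})

test_that("scoring is total: one result per record on a mixed cohort", {
  reg <- generate_registry(sim_config(n_centers = 10), seed = 13)
  dri <- score_dri(reg$patients)
  hct <- score_hct_ci(reg$patients)
  expect_equal(nrow(dri), nrow(reg$patients))
  expect_equal(nrow(hct), nrow(reg$patients))
  expect_false(anyNA(dri$dri_overall))
  expect_true(all(dri$dri_overall %in%
                    c("low", "intermediate", "high", "very_high")))
  expect_true(all(hct$hctci_derivation %in%
                    c("complete", "partial_assumed_absent", "missing")))
  expect_true(all(is.na(hct$hctci_score[hct$hctci_derivation == "missing"])))
  # the imputed flag and the overall level stay consistent
  expect_true(all(dri$dri_overall[dri$dri_imputed] == "intermediate"))
})

test_that("the DRI missingness breakdown recovers injected rates", {
  # no missing fields -> all fractions zero
  p <- make_patients(20, cytogenetics_risk = "favorable")
  bd <- dri_missingness_breakdown(p)
  expect_equal(bd$frac_missing, 0)

  # every AML record lacking cytogenetics -> fraction 1.0
  p <- make_patients(15, cytogenetics_status = "not_done",
                     cytogenetics_risk = NA_character_)
  bd <- dri_missingness_breakdown(p)
  expect_equal(bd$frac_missing, 1)
  expect_equal(bd$frac_cytogenetics, 1)

  # injected 20% cytogenetics missingness in an AML cohort
  cfg <- sim_config(n_centers = 20,
                    covariate_model = list(
                      diagnosis = c(AML = 1),
                      cyto_status = c(normal = 0.5, abnormal_classified = 0.5,
                                      abnormal_no_detail = 0, not_done = 0)),
                    missingness = list(comorbidity = c(0, 0),
                                       cytogenetics = c(0.2, 0.2),
                                       stage = c(0, 0), performance = c(0, 0),
                                       severity_boost = 1, center_range = 0))
  reg <- generate_registry(cfg, seed = 29)
  bd <- dri_missingness_breakdown(reg$patients)
  n_y <- bd$n
  expect_true(all(abs(bd$frac_cytogenetics - 0.2) <
                    4 * sqrt(0.2 * 0.8 / n_y)))
  # by-reason fractions account for the overall fraction exactly
  expect_equal(bd$frac_missing,
               bd$frac_cytogenetics + bd$frac_stage + bd$frac_both)
})
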