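# Synthetic multi-centre registry generator with known ground truth.
#
# Death times follow an exponential hazard within the 1-year horizon:
# rate_i = baseline_hazard * exp(lp_i) * center_effect, with the linear
# predictor built from the same derived covariates (age, DRI, HCT-CI band,
# performance score) that the default case-mix model fits. Loss to
# follow-up is an independent per-centre exponential censoring process;
# administrative censoring occurs at the extraction date. Missingness is
# injected after outcome generation, missing-at-random given transplant
# year, centre and (optionally) observed disease stage, with a linear
# per-year trend emulating improving registry completeness.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic registry. The defaults emulate a
#' plausible allogeneic registry: ~20 transplants/centre/year (log-normal
#' across centres), a constant daily death hazard of 5.5e-4 before
#' case-mix (roughly 18% one-year baseline mortality), moderate loss to
#' follow-up (~4%/year) and case-mix missingness declining over the window
#' (comorbidities 49% -> 9%, cytogenetics 25% -> 7%, stage 3% -> 2.5%).
#'
#' @param n_centers Number of centres.
#' @param transplant_type `"allogeneic"` or `"autologous"`.
#' @param window An [analysis_window()].
#' @param volume_meanlog,volume_sdlog Log-normal parameters of the annual
#'   centre volume.
#' @param baseline_hazard Constant daily death hazard before case-mix.
#' @param coefficients True log hazard ratios: `age_per_decade`,
#'   `perf_per10` and named vectors `dri`, `hctci_band` over the index
#'   levels.
#' @param center_effects Per-centre multiplicative hazard factors
#'   (length `n_centers`; 1.0 = on-model). `NULL` means all 1.
#' @param ltfu_rate Mean per-centre daily censoring hazard for loss to
#'   follow-up; 0 disables it.
#' @param ltfu_sdlog Log-normal spread of the per-centre censoring hazard.
#' @param missingness Named list of `c(start, end)` missing probabilities
#'   (linear in year) for `comorbidity`, `cytogenetics`, `stage`,
#'   `performance`; plus `severity_boost`, a multiplier applied to
#'   patients with advanced observed stage (1 = none), and `center_range`,
#'   the half-width of the uniform per-centre multiplier.
#' @param covariate_model Named list of category probabilities
#'   (`diagnosis`, `stage`, `mds_substage`, `cyto_status`, `cyto_risk`,
#'   comorbidity prevalences, ...); see defaults in the source.
#' @param under_reporting Fraction of activity reported to the registry;
#'   survey counts are generated counts divided by this factor.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_centers = 50L,
                       transplant_type = "allogeneic",
                       window = analysis_window("2015-01-01", "2019-12-31",
                                                "2021-05-14"),
                       volume_meanlog = log(20), volume_sdlog = 0.5,
                       baseline_hazard = 5.5e-4,
                       coefficients = list(
                         age_per_decade = 0.25,
                         perf_per10 = -0.10,
                         dri = c(low = 0, intermediate = 0.35,
                                 high = 0.70, very_high = 1.00),
                         hctci_band = c(low = 0, intermediate = 0.20,
                                        high = 0.45)),
                       center_effects = NULL,
                       ltfu_rate = 1.2e-4, ltfu_sdlog = 0.7,
                       missingness = list(comorbidity = c(0.49, 0.09),
                                          cytogenetics = c(0.25, 0.07),
                                          stage = c(0.03, 0.025),
                                          performance = c(0.20, 0.10),
                                          severity_boost = 1,
                                          center_range = 0.3),
                       covariate_model = NULL,
                       under_reporting = 0.95) {
  transplant_type <- match.arg(transplant_type, .tx_types)
  if (is.null(center_effects)) center_effects <- rep(1, n_centers)
  if (length(center_effects) != n_centers)
    stop("center_effects must have length n_centers")
  if (baseline_hazard < 0 || ltfu_rate < 0) stop("hazards must be >= 0")
  cm <- .default_covariate_model(transplant_type)
  if (!is.null(covariate_model)) cm[names(covariate_model)] <- covariate_model
  structure(list(n_centers = as.integer(n_centers),
                 transplant_type = transplant_type, window = window,
                 volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
                 baseline_hazard = baseline_hazard,
                 coefficients = coefficients,
                 center_effects = center_effects,
                 ltfu_rate = ltfu_rate, ltfu_sdlog = ltfu_sdlog,
                 missingness = missingness, covariate_model = cm,
                 under_reporting = under_reporting),
            class = "sim_config")
}

.default_covariate_model <- function(type) {
  if (type == "allogeneic") {
    diagnosis <- c(AML = 0.32, ALL = 0.10, MDS = 0.12, lymphoma = 0.13,
                   myeloma = 0.06, other_haem = 0.17,
                   bone_marrow_failure = 0.05, inherited_disorder = 0.02,
                   autoimmune = 0.01, histiocytic = 0.005,
                   hemoglobinopathy = 0.015, solid_tumor = 0.01)
    donor <- c(MSD = 0.30, MUD = 0.40, MMUD = 0.10, haplo = 0.15, cord = 0.05)
  } else {
    diagnosis <- c(myeloma = 0.45, lymphoma = 0.38, AML = 0.04, ALL = 0.01,
                   autoimmune = 0.04, other_haem = 0.06, solid_tumor = 0.02)
    donor <- c(auto = 1)
  }
  list(diagnosis = diagnosis,
       stage = c(early = 0.50, intermediate = 0.30, advanced = 0.20),
       mds_substage = c(RAEB1 = 0.25, RAEB2 = 0.25,
                        transformed_AML = 0.10, other = 0.40),
       cyto_status = c(normal = 0.45, abnormal_classified = 0.45,
                       abnormal_no_detail = 0.05, not_done = 0.05),
       cyto_risk_aml = c(favorable = 0.20, intermediate = 0.50, adverse = 0.30),
       cyto_risk_mds = c(favorable = 0, intermediate = 0.60, adverse = 0.40),
       age_mean = 52, age_sd = 12, age_min = 18, age_max = 78,
       performance = stats::setNames(c(0.05, 0.10, 0.25, 0.35, 0.25),
                                     c("60", "70", "80", "90", "100")),
       comorbidity_prev = c(arrhythmia = 0.04, cardiac = 0.06,
                            inflammatory_bowel_disease = 0.01, diabetes = 0.09,
                            cerebrovascular_disease = 0.02,
                            psychiatric_disturbance = 0.06, hepatic_mild = 0.05,
                            obesity = 0.08, infection = 0.07,
                            rheumatologic = 0.02, peptic_ulcer = 0.02,
                            renal_moderate_severe = 0.02,
                            pulmonary_moderate = 0.10, prior_solid_tumor = 0.05,
                            heart_valve_disease = 0.01, pulmonary_severe = 0.05,
                            hepatic_moderate_severe = 0.01),
       donor = donor,
       graft = c(BM = 0.15, PB = 0.80, CB = 0.05),
       conditioning = c(MAC = 0.50, RIC = 0.50),
       molecular_none = c(0.60, 0.25))  # P(no marker) start -> end of window
}

.sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic registry
#'
#' Draws a full multi-centre patient table, the matching activity table
#' and a ground-truth table (true linear predictor, the uncensored
#' 365-day death indicator and the per-centre hazard factor). Output is
#' reproducible bit-for-bit given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed controlling all randomness.
#' @return A list of class `"synthetic_registry"` with elements
#'   `patients`, `activity`, `truth`, `patients_complete` (the oracle
#'   table before missingness injection) and `config`.
#' @export
generate_registry <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_centers < 1) stop("degenerate config: no centres")
  set.seed(seed)
  cm <- config$covariate_model
  win <- config$window
  years <- .window_years(win)
  ny <- length(years)

  centers <- sprintf("C%03d", seq_len(config$n_centers))
  vol <- pmax(1, round(stats::rlnorm(config$n_centers, config$volume_meanlog,
                                     config$volume_sdlog)))
  counts <- matrix(stats::rpois(config$n_centers * ny, rep(vol, ny)),
                   nrow = config$n_centers)  # centre x year
  if (sum(counts) == 0) stop("degenerate config: no patients generated")

  center_ix <- rep(rep(seq_len(config$n_centers), ny), as.vector(counts))
  year_ix <- rep(rep(seq_len(ny), each = config$n_centers), as.vector(counts))
  n <- length(center_ix)
  ord <- order(center_ix, year_ix)
  center_ix <- center_ix[ord]; year_ix <- year_ix[ord]

  year_start <- as.Date(paste0(years, "-01-01"))
  year_len <- as.integer(as.Date(paste0(years, "-12-31")) - year_start)
  tdate <- year_start[year_ix] +
    floor(stats::runif(n) * (year_len[year_ix] + 1))
  tdate <- pmin(pmax(tdate, win$start), win$end)

  diagnosis <- .sample_cat(n, cm$diagnosis)
  stage <- .sample_cat(n, cm$stage)
  mds_sub <- ifelse(diagnosis == "MDS", .sample_cat(n, cm$mds_substage),
                    NA_character_)
  needs_cyto <- diagnosis %in% c("AML", "MDS")
  cyto_status <- ifelse(needs_cyto, .sample_cat(n, cm$cyto_status),
                        NA_character_)
  cyto_risk <- rep(NA_character_, n)
  i <- needs_cyto & cyto_status == "normal"
  cyto_risk[i] <- "intermediate"
  i <- needs_cyto & cyto_status == "abnormal_classified"
  cyto_risk[i & diagnosis == "AML"] <-
    .sample_cat(sum(i & diagnosis == "AML"), cm$cyto_risk_aml)
  cyto_risk[i & diagnosis == "MDS"] <-
    .sample_cat(sum(i & diagnosis == "MDS"), cm$cyto_risk_mds)

  age <- pmin(pmax(stats::rnorm(n, cm$age_mean, cm$age_sd),
                   cm$age_min), cm$age_max)
  sex <- sample(.sexes, n, replace = TRUE)
  perf <- as.integer(.sample_cat(n, cm$performance))
  donor <- .sample_cat(n, cm$donor)
  graft <- .sample_cat(n, cm$graft)
  conditioning <- if (config$transplant_type == "allogeneic")
    .sample_cat(n, cm$conditioning) else rep("MAC", n)

  prev <- cm$comorbidity_prev
  com_mat <- matrix(stats::runif(n * length(prev)) <
                      rep(prev, each = n), nrow = n)
  colnames(com_mat) <- names(prev)
  comorbidities <- apply(com_mat, 1, function(r)
    paste(colnames(com_mat)[r], collapse = ";"))
  comorbidity_any <- ifelse(nzchar(comorbidities), "yes", "no")

  p_none <- cm$molecular_none[1] + (cm$molecular_none[2] - cm$molecular_none[1]) *
    (year_ix - 1) / max(1, ny - 1)
  u <- stats::runif(n)
  n_mol <- ifelse(u < p_none, 0L, ifelse(u < p_none + 0.6 * (1 - p_none), 1L, 2L))

  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    center_code = centers[center_ix],
    transplant_type = config$transplant_type,
    transplant_number = 1L,
    transplant_date = tdate,
    diagnosis = diagnosis, disease_stage = stage, mds_substage = mds_sub,
    cytogenetics_status = cyto_status, cytogenetics_risk = cyto_risk,
    age_years = round(age, 1), sex = sex, performance_score = perf,
    donor_type = donor, graft_source = graft,
    conditioning_intensity = conditioning,
    comorbidity_any = comorbidity_any, comorbidities = comorbidities,
    n_molecular_markers = n_mol,
    last_contact_days = NA_integer_, vital_status = NA_character_,
    death_days = NA_integer_, stringsAsFactors = FALSE)

  # outcome generation from the true linear predictor
  co <- config$coefficients
  dri <- score_dri(patients)
  hct <- score_hct_ci(patients)
  lp <- co$age_per_decade * (age - 55) / 10 +
    co$perf_per10 * (perf - 90) / 10 +
    unname(co$dri[dri$dri_overall]) +
    unname(co$hctci_band[hct$hctci_band])
  ce <- config$center_effects[center_ix]
  rate <- config$baseline_hazard * exp(lp) * ce
  t_death <- ifelse(rate > 0, stats::rexp(n) / rate, Inf)
  ltfu_c <- if (config$ltfu_rate > 0)
    stats::rlnorm(config$n_centers, log(config$ltfu_rate), config$ltfu_sdlog)
  else rep(0, config$n_centers)
  c_rate <- ltfu_c[center_ix]
  t_cens <- ifelse(c_rate > 0, stats::rexp(n) / c_rate, Inf)
  t_admin <- as.numeric(win$extraction - tdate)
  died <- t_death <= pmin(t_cens, t_admin)
  patients$vital_status <- ifelse(died, "dead", "alive")
  # deaths are recorded on the day they occur (rounded up), censoring at
  # the last completed day, so death within t days <=> death_days <= t
  patients$death_days <- ifelse(died, as.integer(ceiling(t_death)),
                                NA_integer_)
  patients$last_contact_days <- ifelse(died, patients$death_days,
                                       as.integer(floor(pmin(t_cens, t_admin))))

  truth <- data.frame(patient_id = patients$patient_id,
                      center_code = patients$center_code,
                      lp = lp, dead365_true = t_death <= 365,
                      center_effect = ce, stringsAsFactors = FALSE)

  patients_complete <- patients  # pre-missingness oracle table
  patients <- .inject_missingness(patients, config, center_ix, year_ix, ny)

  activity <- data.frame(
    center_code = rep(centers, ny),
    year = rep(years, each = config$n_centers),
    transplant_type = config$transplant_type,
    transplants_survey = pmax(as.vector(counts),
                              round(as.vector(counts) / config$under_reporting)),
    full_member = TRUE, stringsAsFactors = FALSE)
  activity <- activity[order(activity$center_code, activity$year), ]
  rownames(activity) <- NULL

  structure(list(patients = patients, activity = activity, truth = truth,
                 patients_complete = patients_complete,
                 config = config, seed = seed),
            class = "synthetic_registry")
}

.inject_missingness <- function(patients, config, center_ix, year_ix, ny) {
  ms <- config$missingness
  boost <- if (is.null(ms$severity_boost)) 1 else ms$severity_boost
  crange <- if (is.null(ms$center_range)) 0 else ms$center_range
  cmult <- stats::runif(config$n_centers, 1 - crange, 1 + crange)
  p_of <- function(se) {
    if (is.null(se)) return(rep(0, nrow(patients)))
    p <- se[1] + (se[2] - se[1]) * (year_ix - 1) / max(1, ny - 1)
    p <- p * cmult[center_ix]
    adv <- !is.na(patients$disease_stage) & patients$disease_stage == "advanced"
    p[adv] <- p[adv] * boost
    pmin(pmax(p, 0), 1)
  }
  hit <- stats::runif(nrow(patients)) < p_of(ms$comorbidity)
  patients$comorbidity_any[hit] <- NA_character_
  patients$comorbidities[hit] <- ""
  hit <- stats::runif(nrow(patients)) < p_of(ms$cytogenetics) &
    patients$diagnosis %in% c("AML", "MDS")
  patients$cytogenetics_status[hit] <- "not_done"
  patients$cytogenetics_risk[hit] <- NA_character_
  hit <- stats::runif(nrow(patients)) < p_of(ms$performance)
  patients$performance_score[hit] <- NA_integer_
  # stage missingness drawn last so the severity boost above is MAR given
  # the observed (pre-deletion) stage of the other variables
  hit <- stats::runif(nrow(patients)) < p_of(ms$stage)
  patients$disease_stage[hit] <- NA_character_
  patients
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat(sprintf("Synthetic %s registry: %d patients, %d centres, %d-%d\n",
              x$config$transplant_type, nrow(x$patients),
              x$config$n_centers, min(.tx_year(x$patients)),
              max(.tx_year(x$patients))))
  invisible(x)
}

#' Toy single-centre cohort with a fixed follow-up fraction
#'
#' Builds `n` adult first-allograft records at one centre, of which
#' `floor(followed_fraction * n)` have a full 365-day follow-up and the
#' remainder are lost at day 0 - a fixture for the follow-up
#' traffic-light logic.
#'
#' @param n Number of patients.
#' @param followed_fraction Fraction in `[0, 1]` with complete follow-up.
#' @param center_code Centre identifier.
#' @param window An [analysis_window()]; transplants are dated at its
#'   start so that every patient has full potential follow-up.
#' @return A patient data frame.
#' @export
make_toy_center <- function(n, followed_fraction, center_code = "TOY",
                            window = analysis_window("2015-01-01",
                                                     "2019-12-31",
                                                     "2021-05-14")) {
  stopifnot(followed_fraction >= 0, followed_fraction <= 1)
  k <- floor(followed_fraction * n)
  data.frame(
    patient_id = sprintf("%s-%03d", center_code, seq_len(n)),
    center_code = center_code, transplant_type = "allogeneic",
    transplant_number = 1L, transplant_date = window$start,
    diagnosis = "AML", disease_stage = "early", mds_substage = NA_character_,
    cytogenetics_status = "normal", cytogenetics_risk = "intermediate",
    age_years = 50, sex = "M", performance_score = 90L,
    donor_type = "MSD", graft_source = "PB", conditioning_intensity = "MAC",
    comorbidity_any = "no", comorbidities = "",
    n_molecular_markers = 0L,
    last_contact_days = c(rep(365L, k), rep(0L, n - k)),
    vital_status = "alive", death_days = NA_integer_,
    stringsAsFactors = FALSE)
}
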