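# Patient and centre selection criteria plus the follow-up-completeness
# gate with traffic-light classification.

#' Eligibility criteria thresholds
#'
#' Loads the packaged `criteria.yaml`: minimum mean annual volumes
#' (inclusive; 10 allografts, 5 autografts), the strict reporting gate
#' (> 0.80 of Activity-Survey counts), the strict follow-up outcome gate
#' (> 0.80 observed/potential) and the traffic-light bands
#' (green > 0.90, red < 0.80, amber otherwise).
#'
#' @param path Optional path to an alternative criteria YAML.
#' @return A list of thresholds.
#' @export
benchmark_criteria <- function(path = NULL) .read_config("criteria.yaml", path)

#' Select patients for benchmarking
#'
#' Keeps first transplants performed inside the analysis window, and
#' excludes solid tumours in allogeneic transplants and non-haematological
#' diagnoses (including solid tumours) and paediatric patients in
#' autologous procedures. Patients who received a second transplant before
#' 1 year are not censored: selection never alters follow-up fields, it
#' only drops the non-first rows themselves.
#'
#' @param patients Patient data frame.
#' @param window An [analysis_window()].
#' @param criteria See [benchmark_criteria()].
#' @return A list with `included` (patient rows kept) and `excluded`
#'   (data frame of `patient_id`, `reasons`, semicolon-separated).
#' @export
select_patients <- function(patients, window,
                            criteria = benchmark_criteria()) {
  n <- nrow(patients)
  reasons <- character(n)
  add <- function(bad, msg) {
    bad[is.na(bad)] <- FALSE
    reasons[bad] <<- ifelse(nzchar(reasons[bad]),
                            paste(reasons[bad], msg, sep = ";"), msg)
  }
  add(patients$transplant_number != 1L, "not_first_transplant")
  add(patients$transplant_date < window$start |
        patients$transplant_date > window$end, "outside_window")
  allo <- patients$transplant_type == "allogeneic"
  auto <- patients$transplant_type == "autologous"
  add(allo & patients$diagnosis == "solid_tumor", "solid_tumor_allo")
  add(auto & patients$diagnosis %in% c("solid_tumor", "non_haem"),
      "non_haem_auto")
  add(auto & patients$age_years < criteria$adult_age, "paediatric_auto")
  keep <- !nzchar(reasons)
  list(included = patients[keep, , drop = FALSE],
       excluded = data.frame(patient_id = patients$patient_id[!keep],
                             reasons = reasons[!keep],
                             stringsAsFactors = FALSE))
}

#' Select centres for benchmarking
#'
#' Applies the centre criteria for one transplant type: full membership,
#' a minimum mean annual registry volume over the window (inclusive
#' threshold), and registry reporting above the Activity-Survey gate
#' (strict, pooled over the window years). A centre with registry records
#' but no activity rows is excluded as under-reporting, with a warning.
#'
#' @param patients Patient data frame (already patient-selected).
#' @param activity Activity data frame, see [read_activity()].
#' @param window An [analysis_window()].
#' @param type `"allogeneic"` or `"autologous"`.
#' @param criteria See [benchmark_criteria()].
#' @return Data frame with one row per centre: `center_code`, `included`,
#'   `reasons`, `mean_annual_volume`, `reporting_ratio`, `full_member`.
#' @export
select_centers <- function(patients, activity, window,
                           type = c("allogeneic", "autologous"),
                           criteria = benchmark_criteria()) {
  type <- match.arg(type)
  pts <- patients[patients$transplant_type == type, , drop = FALSE]
  act <- activity[activity$transplant_type == type &
                    activity$year %in% .window_years(window), , drop = FALSE]
  centers <- sort(unique(pts$center_code))
  nyears <- length(.window_years(window))
  min_vol <- criteria$min_annual_volume[[type]]

  out <- do.call(rbind, lapply(centers, function(cc) {
    n_reg <- sum(pts$center_code == cc)
    a <- act[act$center_code == cc, , drop = FALSE]
    member <- if (nrow(a)) all(a$full_member) else NA
    survey <- sum(a$transplants_survey)
    ratio <- if (nrow(a) && survey > 0) n_reg / survey else NA_real_
    reasons <- character(0)
    if (n_reg / nyears < min_vol) reasons <- c(reasons, "below_volume")
    if (nrow(a) == 0) {
      warning("centre ", cc, " has registry records but no activity rows",
              call. = FALSE)
      reasons <- c(reasons, "under_reporting")
    } else if (!is.na(ratio) && ratio <= criteria$reporting_gate) {
      reasons <- c(reasons, "under_reporting")
    }
    if (!is.na(member) && !member) reasons <- c(reasons, "not_full_member")
    data.frame(center_code = cc, included = length(reasons) == 0,
               reasons = paste(reasons, collapse = ";"),
               mean_annual_volume = n_reg / nyears,
               reporting_ratio = ratio,
               full_member = isTRUE(member), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assess follow-up completeness of one centre
#'
#' Per patient, the potential follow-up is `min(horizon, extraction -
#' transplant date)` days; the observed follow-up equals the potential one
#' for patients who died within it (a dead patient cannot be lost), and
#' otherwise `min(last contact, potential)`, or 0 when the last contact is
#' missing. The centre ratio is total observed over total potential, with
#' traffic lights green > 0.90, red < 0.80, amber otherwise.
#'
#' @param patients Patient rows of a single centre (patient-selected).
#' @param window An [analysis_window()].
#' @param criteria See [benchmark_criteria()].
#' @return A list of class `"followup_assessment"`: `center_code`,
#'   `observed_fu_days`, `potential_fu_days`, `ratio`, `traffic_light`.
#' @export
assess_followup <- function(patients, window,
                            criteria = benchmark_criteria()) {
  if (length(unique(patients$center_code)) > 1)
    stop("assess_followup() expects the records of a single centre")
  potential <- pmin(window$horizon_days,
                    as.numeric(window$extraction - patients$transplant_date))
  if (any(potential <= 0)) {
    warning("record(s) with no potential follow-up excluded from the ratio",
            call. = FALSE)
    keep <- potential > 0
    patients <- patients[keep, , drop = FALSE]
    potential <- potential[keep]
  }
  dead_within <- !is.na(patients$vital_status) &
    patients$vital_status == "dead" &
    !is.na(patients$death_days) & patients$death_days <= potential
  lc <- patients$last_contact_days
  lc[is.na(lc)] <- 0
  observed <- ifelse(dead_within, potential, pmin(lc, potential))
  ratio <- sum(observed) / sum(potential)
  structure(list(center_code = patients$center_code[1],
                 observed_fu_days = sum(observed),
                 potential_fu_days = sum(potential),
                 ratio = ratio,
                 traffic_light = traffic_light(ratio, criteria)),
            class = "followup_assessment")
}

#' @export
print.followup_assessment <- function(x, ...) {
  cat(sprintf("Centre %s: follow-up ratio %.3f (%s)\n",
              x$center_code, x$ratio, x$traffic_light))
  invisible(x)
}

#' Traffic-light classification of a follow-up ratio
#'
#' @param ratio Observed/potential follow-up ratio in `[0, 1]`.
#' @param criteria See [benchmark_criteria()].
#' @return `"green"` (> 0.90), `"red"` (< 0.80) or `"amber"`.
#' @export
traffic_light <- function(ratio, criteria = benchmark_criteria()) {
  tl <- criteria$traffic_light
  ifelse(ratio > tl$green_above, "green",
         ifelse(ratio < tl$red_below, "red", "amber"))
}

# Follow-up assessment for every centre at once; returns a data frame.
assess_followup_by_center <- function(patients, window,
                                      criteria = benchmark_criteria()) {
  out <- do.call(rbind, lapply(split(patients, patients$center_code),
                               function(p) {
    a <- assess_followup(p, window, criteria)
    data.frame(center_code = a$center_code, n = nrow(p),
               observed_fu_days = a$observed_fu_days,
               potential_fu_days = a$potential_fu_days,
               ratio = a$ratio, traffic_light = a$traffic_light,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
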