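# Composite case-mix indices: HCT-CI (weighted comorbidity sum) and the
# adapted Disease Risk Index, both driven by editable YAML tables.

.config_env <- new.env(parent = emptyenv())

.read_config <- function(name, path = NULL) {
  if (is.null(path)) {
    key <- name
    if (!is.null(.config_env[[key]])) return(.config_env[[key]])
    path <- system.file("extdata", name, package = "hsctbench")
    cfg <- yaml::read_yaml(path)
    .config_env[[key]] <- cfg
    return(cfg)
  }
  yaml::read_yaml(path)
}

#' HCT-CI comorbidity weights
#'
#' Default integer weights for the 17 comorbidity categories, loaded from
#' the packaged `hctci_weights.yaml` (editable and versioned).
#'
#' @param path Optional path to an alternative weights YAML.
#' @return Named integer vector of weights.
#' @export
hctci_weights <- function(path = NULL) {
  cfg <- .read_config("hctci_weights.yaml", path)
  w <- unlist(cfg$weights)
  storage.mode(w) <- "integer"
  w
}

#' Adapted Disease Risk Index lookup table
#'
#' The disease-group, stage-group and overall-risk lookup used by
#' [score_dri()], loaded from the packaged `dri_table.yaml`.
#'
#' @param path Optional path to an alternative lookup YAML.
#' @return A list mirroring the YAML structure.
#' @export
dri_table <- function(path = NULL) .read_config("dri_table.yaml", path)

#' Score the HCT-CI
#'
#' Computes the HCT-specific Comorbidity Index from the raw comorbidity
#' fields. The reporting convention is: if a centre states that no
#' comorbidity is present the score is 0 (derivation `complete`); if any
#' comorbidity is flagged present, at least one must be entered and the
#' unlisted ones are assumed absent (derivation `partial_assumed_absent`);
#' a present flag with no entries, or a missing flag, leaves the score
#' undefined (derivation `missing`, to be imputed downstream).
#'
#' @param patients Patient data frame.
#' @param weights Named integer weights, see [hctci_weights()].
#' @return Data frame with `patient_id`, `hctci_score`, `hctci_band`
#'   (`low` = 0, `intermediate` = 1-2, `high` = 3+) and
#'   `hctci_derivation`.
#' @export
score_hct_ci <- function(patients, weights = hctci_weights()) {
  labels <- .split_comorbidities(patients$comorbidities)
  unknown <- unlist(lapply(labels, setdiff, y = names(weights)))
  if (length(unknown))
    stop("unknown comorbidity label: '", unknown[1], "'")
  n_listed <- lengths(labels)
  score <- vapply(labels, function(l) sum(weights[l]), numeric(1))
  any_flag <- patients$comorbidity_any

  derivation <- rep("missing", nrow(patients))
  derivation[!is.na(any_flag) & any_flag == "no" & n_listed == 0] <- "complete"
  derivation[n_listed > 0] <- "partial_assumed_absent"
  score[derivation == "missing"] <- NA_real_
  score[derivation == "complete"] <- 0

  band <- rep(NA_character_, length(score))
  band[!is.na(score) & score == 0] <- "low"
  band[!is.na(score) & score >= 1 & score <= 2] <- "intermediate"
  band[!is.na(score) & score >= 3] <- "high"

  data.frame(patient_id = patients$patient_id,
             hctci_score = as.integer(score),
             hctci_band = band,
             hctci_derivation = derivation,
             stringsAsFactors = FALSE)
}

#' Score the adapted Disease Risk Index
#'
#' Applies, in order: (1) the five extra diagnostic groups (bone marrow
#' failure, inherited disorders, autoimmune diseases, histiocytic
#' disorders, hemoglobinopathies) are classified overall low risk;
#' (2) MDS is split by substage - RAEB-1, RAEB-2 and transformation to AML
#' are not low-risk MDS, every other substage is low-risk MDS (disease
#' group low, no cytogenetics needed); (3) where cytogenetics are required
#' (AML, non-low-risk MDS) but missing - no chromosome analysis registered,
#' or abnormal with no further detail - the overall index is imputed
#' `intermediate` and flagged; (4) likewise for missing disease stage;
#' (5) otherwise the overall risk is the lookup of disease group by stage
#' group. The index depends only on diagnosis, stage and cytogenetics.
#'
#' @param patients Patient data frame.
#' @param table Lookup list, see [dri_table()].
#' @return Data frame with `patient_id`, `dri_disease_group`,
#'   `dri_stage_group`, `dri_overall`
#'   (`low`/`intermediate`/`high`/`very_high`), `dri_imputed` and
#'   `dri_missing_reason` (`none`/`cytogenetics`/`stage`/`both`).
#' @export
score_dri <- function(patients, table = dri_table()) {
  n <- nrow(patients)
  dx <- patients$diagnosis
  known <- c(table$low_risk_diagnoses, "AML", "MDS", names(table$disease_groups))
  bad <- !is.na(dx) & !(dx %in% known)
  if (any(bad)) stop("diagnosis not covered by the DRI lookup: '", dx[bad][1], "'")
  if (any(is.na(dx))) stop("diagnosis is mandatory for DRI scoring")

  extra_low <- dx %in% table$low_risk_diagnoses
  is_mds <- dx == "MDS"
  mds_high <- is_mds & !is.na(patients$mds_substage) &
    patients$mds_substage %in% c("RAEB1", "RAEB2", "transformed_AML")
  mds_low <- is_mds & !is.na(patients$mds_substage) & !mds_high

  cyto_missing_val <- is.na(patients$cytogenetics_risk) |
    (!is.na(patients$cytogenetics_status) &
       patients$cytogenetics_status %in% c("abnormal_no_detail", "not_done"))
  need_cyto <- (dx == "AML" | mds_high) & !extra_low
  miss_cyto <- need_cyto & cyto_missing_val
  miss_stage <- !extra_low &
    (is.na(patients$disease_stage) | (is_mds & is.na(patients$mds_substage)))

  group <- rep(NA_character_, n)
  group[extra_low] <- "low"
  group[mds_low] <- table$mds_lowrisk_group
  idx <- dx == "AML" & !miss_cyto
  group[idx] <- unlist(table$aml_by_cytogenetics)[patients$cytogenetics_risk[idx]]
  idx <- mds_high & !miss_cyto
  group[idx] <- unlist(table$mds_highrisk_by_cytogenetics)[patients$cytogenetics_risk[idx]]
  idx <- dx %in% names(table$disease_groups)
  group[idx] <- unlist(table$disease_groups)[dx[idx]]

  stage_group <- rep(NA_character_, n)
  ok_stage <- !is.na(patients$disease_stage)
  stage_group[ok_stage] <- unlist(table$stage_groups)[patients$disease_stage[ok_stage]]

  imputed <- !extra_low & (miss_cyto | miss_stage)
  reason <- rep("none", n)
  reason[miss_cyto & !miss_stage] <- "cytogenetics"
  reason[!miss_cyto & miss_stage] <- "stage"
  reason[miss_cyto & miss_stage] <- "both"
  reason[extra_low] <- "none"

  overall <- rep(NA_character_, n)
  overall[extra_low] <- "low"
  overall[imputed] <- table$imputed_overall
  rest <- !extra_low & !imputed
  if (any(rest)) {
    ov <- table$overall
    overall[rest] <- mapply(function(g, s) ov[[g]][[s]],
                            group[rest], stage_group[rest])
  }

  data.frame(patient_id = patients$patient_id,
             dri_disease_group = group,
             dri_stage_group = stage_group,
             dri_overall = overall,
             dri_imputed = imputed,
             dri_missing_reason = reason,
             stringsAsFactors = FALSE)
}

#' Per-year breakdown of undefined DRI
#'
#' Summarises, per transplant year, the fraction of records whose DRI had
#' to be imputed, split by reason (missing cytogenetics, missing stage,
#' both). A record missing both is counted once in the overall fraction
#' and reported separately under `frac_both`.
#'
#' @param patients Patient data frame (with transplant dates).
#' @param dri Result of [score_dri()] on `patients`; computed if omitted.
#' @return Data frame with one row per year: `year`, `n`, `frac_missing`,
#'   `frac_cytogenetics`, `frac_stage`, `frac_both`.
#' @export
dri_missingness_breakdown <- function(patients, dri = score_dri(patients)) {
  year <- .tx_year(patients)
  out <- do.call(rbind, lapply(sort(unique(year)), function(y) {
    i <- year == y
    r <- dri$dri_missing_reason[i]
    data.frame(year = y, n = sum(i),
               frac_missing = mean(r != "none"),
               frac_cytogenetics = mean(r == "cytogenetics"),
               frac_stage = mean(r == "stage"),
               frac_both = mean(r == "both"))
  }))
  rownames(out) <- NULL
  out
}
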