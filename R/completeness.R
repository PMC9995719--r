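# Data-completeness summaries per transplant year and the
# report-distribution ledger arithmetic.

#' Data completeness by transplant year
#'
#' Per year: the fraction of records with each raw case-mix variable
#' missing; the three-way split of the composite indices - HCT-CI
#' complete (no comorbidity reported), partially missing (some
#' comorbidities entered, the rest assumed absent) or totally missing,
#' with `hctci_available` = complete + partial (the score is computable);
#' DRI complete (not imputed) versus imputed by reason; and the
#' molecular-marker reporting split (none / one / more than one).
#' Every fraction set sums to 1.
#'
#' @param patients Patient data frame.
#' @param dri,hctci Optional precomputed scores (computed if omitted).
#' @return Data frame with one row per year.
#' @export
completeness_by_year <- function(patients, dri = score_dri(patients),
                                 hctci = score_hct_ci(patients)) {
  year <- .tx_year(patients)
  aml_mds <- patients$diagnosis %in% c("AML", "MDS")
  cyto_missing <- is.na(patients$cytogenetics_risk) |
    (!is.na(patients$cytogenetics_status) &
       patients$cytogenetics_status %in% c("abnormal_no_detail", "not_done"))
  nmol <- patients$n_molecular_markers
  nmol[is.na(nmol)] <- 0L

  out <- do.call(rbind, lapply(sort(unique(year)), function(y) {
    i <- year == y
    der <- hctci$hctci_derivation[i]
    imp <- dri$dri_imputed[i]
    reason <- dri$dri_missing_reason[i]
    amm <- aml_mds & i
    data.frame(
      year = y, n = sum(i),
      missing_stage = mean(is.na(patients$disease_stage[i])),
      missing_cytogenetics_aml_mds =
        if (any(amm)) mean(cyto_missing[amm]) else 0,
      missing_performance = mean(is.na(patients$performance_score[i])),
      missing_conditioning = mean(is.na(patients$conditioning_intensity[i])),
      missing_comorbidity = mean(is.na(patients$comorbidity_any[i]) |
                                   (patients$comorbidity_any[i] == "yes" &
                                      !nzchar(patients$comorbidities[i]))),
      hctci_complete = mean(der == "complete"),
      hctci_partial = mean(der == "partial_assumed_absent"),
      hctci_missing = mean(der == "missing"),
      hctci_available = mean(der != "missing"),
      dri_complete = mean(!imp),
      dri_missing_cytogenetics = mean(reason == "cytogenetics"),
      dri_missing_stage = mean(reason == "stage"),
      dri_missing_both = mean(reason == "both"),
      molecular_none = mean(nmol[i] == 0),
      molecular_one = mean(nmol[i] == 1),
      molecular_more = mean(nmol[i] > 1))
  }))
  rownames(out) <- NULL
  out
}

.round_half_up <- function(x) floor(x + 0.5)

#' Report-distribution ledger
#'
#' Derives the distribution accounting from the raw counts: successful
#' notifications = total - reports without a PI email - bounced emails;
#' reports not picked up = successful - picked up. Percentages are
#' half-up-rounded integers; the successful percentage is relative to the
#' total, pick-up percentages are relative to the successful
#' notifications. Inconsistent inputs (any derived count negative) abort.
#'
#' @param total Total reports produced.
#' @param no_pi_email Reports with no usable PI email.
#' @param bounced Bounced notifications.
#' @param picked_up Reports picked up.
#' @return A list of class `"distribution_ledger"` with the derived
#'   counts and percentages.
#' @export
distribution_ledger <- function(total, no_pi_email, bounced, picked_up) {
  counts <- c(total = total, no_pi_email = no_pi_email, bounced = bounced,
              picked_up = picked_up)
  if (any(counts < 0)) stop("counts must be non-negative")
  successful <- total - no_pi_email - bounced
  if (successful < 0) stop("inconsistent inputs: successful count negative")
  not_picked_up <- successful - picked_up
  if (not_picked_up < 0) stop("inconsistent inputs: picked_up exceeds successful")
  pct <- function(x, denom) if (denom > 0) .round_half_up(100 * x / denom) else 0
  structure(list(
    total = total, no_pi_email = no_pi_email, bounced = bounced,
    successful = successful, picked_up = picked_up,
    not_picked_up = not_picked_up,
    pct_no_pi_email = pct(no_pi_email, total),
    pct_bounced = pct(bounced, total),
    pct_successful = pct(successful, total),
    pct_picked_up = pct(picked_up, successful),
    pct_not_picked_up = pct(not_picked_up, successful)),
    class = "distribution_ledger")
}

#' @export
print.distribution_ledger <- function(x, ...) {
  cat(sprintf(paste0("Report distribution: %d total; %d successful (%d%%); ",
                     "%d picked up (%d%%), %d not picked up (%d%%)\n"),
              x$total, x$successful, x$pct_successful,
              x$picked_up, x$pct_picked_up,
              x$not_picked_up, x$pct_not_picked_up))
  invisible(x)
}
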