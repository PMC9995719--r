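# The case-mix model: a proportional-hazards fit for 1-year mortality on
# multiply-imputed data, pooled by Rubin's rules, with a Breslow baseline
# cumulative hazard averaged across imputations; plus the per-patient
# expected event probability used for O/E benchmarking.

#' Build the case-mix covariate frame
#'
#' Derives the default model covariates from a patient table and its risk
#' scores: `age_decade` (age centred at 55, per 10 years), `perf10`
#' (performance score centred at 90, per 10 points), `dri_overall` and
#' `hctci_band` as factors with fixed level order, plus the follow-up
#' time (`time_days`) and death indicator (`event`) used downstream.
#' Records with a missing last contact contribute zero follow-up.
#'
#' @param patients Patient data frame.
#' @param dri,hctci Optional precomputed [score_dri()] / [score_hct_ci()]
#'   results (computed if omitted).
#' @return Data frame with one row per patient.
#' @export
casemix_frame <- function(patients, dri = score_dri(patients),
                          hctci = score_hct_ci(patients)) {
  lc <- patients$last_contact_days
  lc[is.na(lc)] <- 0L
  data.frame(
    patient_id = patients$patient_id,
    center_code = patients$center_code,
    age_decade = (patients$age_years - 55) / 10,
    perf10 = (patients$performance_score - 90) / 10,
    dri_overall = factor(dri$dri_overall,
                         levels = c("low", "intermediate", "high", "very_high")),
    hctci_band = factor(hctci$hctci_band,
                        levels = c("low", "intermediate", "high")),
    conditioning_intensity = factor(patients$conditioning_intensity,
                                    levels = .conditioning),
    time_days = as.numeric(lc),
    event = !is.na(patients$vital_status) & patients$vital_status == "dead",
    stringsAsFactors = FALSE)
}

#' Fit the case-mix model
#'
#' Fits a Cox proportional-hazards model for death within the horizon to
#' each imputed dataset (Breslow ties), pools the coefficients by Rubin's
#' rules and averages the Breslow baseline cumulative hazards across
#' imputations on a common time grid. Follow-up is truncated at the
#' horizon; reference levels carry coefficient 0 by construction.
#'
#' @param formula Right-hand-side formula of case-mix covariates, e.g.
#'   `~ age_decade + dri_overall + hctci_band + perf10`; `~ 1` fits the
#'   baseline hazard alone.
#' @param imputed List of completed data frames (e.g. a
#'   [mice_impute()] result), or a single data frame.
#' @param time Follow-up days per patient.
#' @param event Logical death indicators.
#' @param horizon_days Outcome horizon (default 365).
#' @return An object of class `"casemix_fit"`: pooled `coefficients`,
#'   pooled `se` and `vcov` (within + between components `W`, `B`),
#'   `basehaz` (data frame of `time`, `hazard`), the evaluable
#'   `basehaz_fun`, factor `xlevels`, `m`, `n` and `events`.
#' @export
fit_casemix <- function(formula, imputed, time, event, horizon_days = 365L) {
  if (is.data.frame(imputed)) imputed <- list(imputed)
  m <- length(imputed)
  stopifnot(m >= 1)
  t365 <- pmin(time, horizon_days)
  e365 <- as.logical(event) & time <= horizon_days
  full <- stats::as.formula(paste(".surv_ ~",
                                  paste(deparse(formula[[2]]), collapse = " ")))
  environment(full) <- environment()

  fits <- lapply(seq_len(m), function(i) {
    dat <- as.data.frame(imputed[[i]])
    for (v in all.vars(formula))
      if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    if (anyNA(dat[all.vars(formula)]))
      stop("imputed dataset ", i, " still contains missing covariate values")
    dat$.surv_ <- survival::Surv(t365, e365)
    fit <- survival::coxph(full, data = dat, ties = "breslow",
                           model = TRUE, x = FALSE)
    if (length(fit$coefficients)) {
      bad <- !is.finite(fit$coefficients) |
        abs(fit$coefficients) > 15 | !is.finite(sqrt(diag(fit$var)))
      if (any(bad))
        stop("covariate '", names(fit$coefficients)[bad][1],
             "' is separated or non-converged in imputation ", i)
    }
    fit
  })

  p <- length(fits[[1]]$coefficients)
  if (p > 0) {
    coefs <- do.call(rbind, lapply(fits, stats::coef))
    qbar <- colMeans(coefs)
    Wbar <- Reduce(`+`, lapply(fits, stats::vcov)) / m
    B <- if (m > 1) stats::cov(coefs) else matrix(0, p, p,
                                                  dimnames = dimnames(Wbar))
    Tmat <- Wbar + (1 + 1 / m) * B
    se <- sqrt(diag(Tmat))
  } else {
    qbar <- numeric(0); Wbar <- B <- Tmat <- matrix(0, 0, 0); se <- numeric(0)
  }

  # Breslow baseline at covariate value zero, averaged across imputations
  grid <- sort(unique(unlist(lapply(fits, function(f)
    survival::basehaz(f, centered = FALSE)$time))))
  Hmat <- vapply(fits, function(f) {
    bh <- survival::basehaz(f, centered = FALSE)
    stats::stepfun(bh$time, c(0, bh$hazard), right = FALSE)(grid)
  }, numeric(length(grid)))
  Hbar <- if (length(grid)) rowMeans(matrix(Hmat, nrow = length(grid)))
          else numeric(0)
  bh_fun <- if (length(grid)) stats::stepfun(grid, c(0, Hbar), right = FALSE)
            else function(t) rep(0, length(t))

  structure(list(coefficients = qbar, se = se, vcov = Tmat, W = Wbar, B = B,
                 basehaz = data.frame(time = grid, hazard = Hbar),
                 basehaz_fun = bh_fun, formula = formula,
                 xlevels = fits[[1]]$xlevels, m = m, n = length(t365),
                 events = sum(e365), horizon_days = horizon_days),
            class = "casemix_fit")
}

#' @export
print.casemix_fit <- function(x, ...) {
  cat(sprintf("Case-mix proportional-hazards fit: n = %d, events = %d, m = %d imputation(s)\n",
              x$n, x$events, x$m))
  if (length(x$coefficients)) {
    print(round(data.frame(coef = x$coefficients, HR = exp(x$coefficients),
                           se = x$se), 4))
  } else cat("(baseline hazard only)\n")
  invisible(x)
}

#' @export
coef.casemix_fit <- function(object, ...) object$coefficients

#' @export
vcov.casemix_fit <- function(object, ...) object$vcov

#' @export
summary.casemix_fit <- function(object, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = names(object$coefficients),
                    coef = unname(object$coefficients),
                    se = unname(object$se))
  out$hr <- exp(out$coef)
  out$hr_lower <- exp(out$coef - z * out$se)
  out$hr_upper <- exp(out$coef + z * out$se)
  out$z <- out$coef / out$se
  out$p_value <- 2 * stats::pnorm(-abs(out$z))
  structure(list(table = out, n = object$n, events = object$events,
                 m = object$m, conf_level = conf_level),
            class = "summary.casemix_fit")
}

#' @export
print.summary.casemix_fit <- function(x, ...) {
  cat(sprintf("Pooled case-mix hazard ratios (n = %d, events = %d, m = %d):\n",
              x$n, x$events, x$m))
  print(cbind(x$table["term"], round(x$table[-1], 4)), row.names = FALSE)
  invisible(x)
}

# Linear predictor of a casemix_fit on new data, checking factor levels.
.casemix_lp <- function(fit, newdata) {
  if (!length(fit$coefficients)) return(rep(0, nrow(newdata)))
  dat <- as.data.frame(newdata)
  for (v in names(fit$xlevels)) {
    x <- as.character(dat[[v]])
    bad <- !is.na(x) & !(x %in% fit$xlevels[[v]])
    if (any(bad))
      stop("level '", x[bad][1], "' of '", v, "' is absent from the fit")
    dat[[v]] <- factor(x, levels = fit$xlevels[[v]])
  }
  if (anyNA(dat[all.vars(fit$formula)]))
    stop("newdata contains missing covariate values; impute first")
  mm <- stats::model.matrix(fit$formula, data = dat)
  mm <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
  drop(mm[, names(fit$coefficients), drop = FALSE] %*% fit$coefficients)
}

#' Expected death probability within the horizon
#'
#' For each patient, `p = 1 - exp(-Lambda0(tau) * exp(lp))`, where
#' `Lambda0` is the pooled Breslow baseline cumulative hazard and `tau`
#' the patient's evaluation time: the full horizon for patients who died
#' within it (a death is fully observed), and the censoring time
#' otherwise - this is how centre follow-up enters the expected counts.
#'
#' @param fit A [fit_casemix()] object.
#' @param newdata Completed (single-value-imputed) covariate frame.
#' @param tau Evaluation time in days per patient; defaults to the
#'   horizon for everyone.
#' @return Data frame with `tau`, `lp` and `p_expected` per row of
#'   `newdata`.
#' @export
expected_probability <- function(fit, newdata,
                                 tau = rep(fit$horizon_days, nrow(newdata))) {
  stopifnot(length(tau) == nrow(newdata), all(tau >= 0),
            all(tau <= fit$horizon_days))
  lp <- .casemix_lp(fit, newdata)
  p <- 1 - exp(-fit$basehaz_fun(tau) * exp(lp))
  data.frame(tau = tau, lp = lp, p_expected = p)
}

#' @export
#' @rdname expected_probability
#' @param object,... Method arguments (`predict`).
predict.casemix_fit <- function(object, newdata,
                                tau = rep(object$horizon_days, nrow(newdata)),
                                ...) {
  expected_probability(object, newdata, tau)
}

# Evaluation time per the follow-up adjustment convention: deaths within
# the horizon count as fully observed (tau = horizon), censored patients
# contribute their censoring time.
.eval_tau <- function(time, event, horizon_days = 365L) {
  dead <- as.logical(event) & time <= horizon_days
  ifelse(dead, horizon_days, pmin(time, horizon_days))
}
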