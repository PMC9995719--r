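# Imputation machinery: the Nelson-Aalen outcome carrier, multiple
# imputation by chained equations (for model estimation) and single-value
# imputation among 12-month survivors (for benchmark prediction).

#' Nelson-Aalen cumulative hazard estimator
#'
#' H(t) = sum over event times t_i <= t of d_i / n_i, with ties aggregated
#' at equal times. The returned object carries the step function and the
#' risk-set table.
#'
#' @param times Non-negative follow-up times (days).
#' @param events Logical/0-1 event indicators.
#' @return Object of class `"nelson_aalen"` with elements `time`,
#'   `n_risk`, `n_event`, `H` (cumulative hazard at each event time) and
#'   `fun`, a right-continuous step function with `H(0-) = 0`.
#' @export
nelson_aalen <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (any(times < 0)) stop("times must be non-negative")
  events <- as.logical(events)
  et <- sort(unique(times[events]))
  if (length(et) == 0) {
    return(structure(list(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), H = numeric(0),
                          fun = function(t) rep(0, length(t))),
                     class = "nelson_aalen"))
  }
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events), numeric(1))
  H <- cumsum(n_event / n_risk)
  structure(list(time = et, n_risk = as.integer(n_risk),
                 n_event = as.integer(n_event), H = H,
                 fun = stats::stepfun(et, c(0, H), right = FALSE)),
            class = "nelson_aalen")
}

#' @export
print.nelson_aalen <- function(x, ...) {
  cat(sprintf("Nelson-Aalen estimator: %d event time(s), H(max) = %.4f\n",
              length(x$time), if (length(x$H)) max(x$H) else 0))
  invisible(x)
}

# Bayesian linear-regression draw (the classical "norm" conditional model):
# draws sigma^2 from its scaled inverse-chi-square posterior and beta from
# its conditional normal, then imputes with added residual noise.
.norm_draw <- function(y, X, Xmis) {
  qrX <- qr(X)
  beta_hat <- qr.coef(qrX, y)
  beta_hat[is.na(beta_hat)] <- 0
  res <- y - X %*% beta_hat
  df <- max(1, length(y) - qrX$rank)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qrX)
  keep <- diag(R) != 0
  V <- try(chol2inv(R[keep, keep, drop = FALSE]), silent = TRUE)
  if (inherits(V, "try-error")) V <- diag(1e-8, sum(keep))
  beta <- beta_hat
  beta[keep] <- beta_hat[keep] +
    drop(t(chol(V * sigma2 + diag(1e-10, sum(keep)))) %*%
           stats::rnorm(sum(keep)))
  drop(Xmis %*% beta) + stats::rnorm(nrow(Xmis), 0, sqrt(sigma2))
}

# Polytomous conditional draw: bootstrap the observed rows (an approximate
# proper-imputation device), fit a multinomial logistic model and sample
# each missing entry from its fitted category probabilities.
.polyreg_draw <- function(y, dat_obs, dat_mis) {
  lev <- levels(droplevels(y))
  if (length(lev) < 2) return(factor(rep(lev, nrow(dat_mis)), levels = levels(y)))
  bs <- sample(nrow(dat_obs), replace = TRUE)
  fit_dat <- cbind(.y = droplevels(y)[bs], dat_obs[bs, , drop = FALSE])
  fit <- nnet::multinom(.y ~ ., data = fit_dat, trace = FALSE, maxit = 200)
  p <- stats::predict(fit, newdata = dat_mis, type = "probs")
  if (is.null(dim(p))) {
    if (length(lev) == 2) p <- cbind(1 - p, p) else p <- matrix(p, nrow = 1)
  }
  colnames(p) <- if (length(lev) == 2 && ncol(p) == 2) lev else colnames(p)
  draw <- apply(p, 1, function(pr) sample(colnames(p), 1, prob = pr))
  factor(draw, levels = levels(y))
}

#' Multiple imputation by chained equations
#'
#' Imputes missing values in the declared case-mix variables by cycling a
#' fixed variable order for a number of sweeps. Each conditional model
#' regresses one variable on all other case-mix variables plus the two
#' outcome carriers: the marginal Nelson-Aalen cumulative hazard evaluated
#' at the patient's (horizon-truncated) follow-up time, and the event
#' indicator. Continuous variables use Bayesian normal-model draws;
#' categorical variables use bootstrap multinomial-logistic draws.
#' Deterministic given `seed`.
#'
#' @param data Data frame; missingness only in `vars`.
#' @param vars Character vector of case-mix variables to impute/cycle.
#' @param time Follow-up days per patient (complete).
#' @param event Logical death indicators (complete).
#' @param predictors Case-mix variables used as predictors (defaults to
#'   `vars`); complete variables listed here enter every conditional
#'   model without being cycled (the full predictor matrix).
#' @param m Number of imputed datasets (default 5).
#' @param iterations Chained-equation sweeps per dataset (default 10).
#' @param seed Integer seed.
#' @param horizon_days Truncation horizon for the outcome carriers.
#' @return A list of `m` completed data frames (class `"mice_result"`),
#'   with attributes `m`, `iterations`, `seed`.
#' @export
mice_impute <- function(data, vars, time, event, predictors = vars,
                        m = 5L, iterations = 10L,
                        seed = 1L, horizon_days = 365L) {
  stopifnot(m >= 1, iterations >= 1, length(time) == nrow(data),
            length(event) == nrow(data))
  if (anyNA(time) || anyNA(event))
    stop("outcome columns must be complete")
  allvars <- union(predictors, vars)
  stopifnot(all(allvars %in% names(data)))
  bad_pred <- setdiff(allvars, vars)
  bad_pred <- bad_pred[vapply(data[bad_pred], anyNA, logical(1))]
  if (length(bad_pred))
    stop("predictor-only variable(s) with missing values: ",
         paste(bad_pred, collapse = ", "))
  t365 <- pmin(time, horizon_days)
  e365 <- as.logical(event) & time <= horizon_days
  na_fit <- nelson_aalen(t365, e365)
  carriers <- data.frame(.na_H = na_fit$fun(t365), .event = as.numeric(e365))

  work <- data[allvars]
  is_cat <- !vapply(work, is.numeric, logical(1))
  for (v in allvars[is_cat[allvars]])
    work[[v]] <- factor(work[[v]])
  na_mask <- lapply(work, is.na)
  all_missing <- vars[vapply(work[vars], function(x) all(is.na(x)),
                             logical(1))]
  if (length(all_missing))
    stop("variable '", all_missing[1],
         "' is entirely missing and cannot be initialized")
  cycle <- vars[vapply(work[vars], anyNA, logical(1))]

  set.seed(seed)
  out <- vector("list", m)
  for (im in seq_len(m)) {
    cur <- work
    for (v in cycle) {  # initialize from the observed margins
      mis <- na_mask[[v]]
      cur[[v]][mis] <- sample(cur[[v]][!mis], sum(mis), replace = TRUE)
    }
    if (length(cycle)) {
      for (it in seq_len(iterations)) {
        for (v in cycle) {
          mis <- na_mask[[v]]
          preds <- cbind(cur[setdiff(allvars, v)], carriers)
          if (is_cat[[v]]) {
            cur[[v]][mis] <- .polyreg_draw(work[[v]][!mis],
                                           preds[!mis, , drop = FALSE],
                                           preds[mis, , drop = FALSE])
          } else {
            X <- stats::model.matrix(~ ., data = preds)
            cur[[v]][mis] <- .norm_draw(work[[v]][!mis],
                                        X[!mis, , drop = FALSE],
                                        X[mis, , drop = FALSE])
          }
        }
      }
    }
    completed <- data
    for (v in vars) {
      x <- if (is_cat[[v]]) as.character(cur[[v]]) else cur[[v]]
      if (is.factor(data[[v]]))
        x <- factor(x, levels = levels(data[[v]]))
      completed[[v]] <- x
    }
    out[[im]] <- completed
  }
  structure(out, class = "mice_result", m = m, iterations = iterations,
            seed = seed)
}

#' Single-value imputation among 12-month survivors
#'
#' Replaces each missing continuous value by the median and each missing
#' categorical value by the mode, computed once over the 12-month
#' survivors of the benchmarked cohort (patients alive with at least
#' `horizon` days of follow-up). Mode ties are broken lexicographically on
#' the category label. Observed values are never changed. Drawing the
#' reference statistics from this relatively healthy sub-population lowers
#' the expected death probability of incompletely reported patients,
#' pushing the centre's O/E ratio upward - the documented incentive to
#' complete the data.
#'
#' @param data Data frame to complete.
#' @param survivors Logical mask of 12-month survivors.
#' @param vars Variables to impute; defaults to every column with
#'   missingness.
#' @return Completed data frame with attribute `"imputed_values"`, the
#'   named list of reference statistics used.
#' @export
single_value_impute <- function(data, survivors,
                                vars = names(which(vapply(data, anyNA,
                                                          logical(1))))) {
  stopifnot(length(survivors) == nrow(data))
  used <- list()
  for (v in vars) {
    obs <- data[[v]][survivors & !is.na(data[[v]])]
    if (length(obs) == 0)
      stop("no 12-month survivor values available for variable '", v, "'")
    val <- if (is.numeric(obs)) {
      stats::median(obs)
    } else {
      tab <- table(as.character(obs))  # names sorted: first max = lexicographic tie-break
      names(tab)[which.max(tab)]
    }
    used[[v]] <- val
    data[[v]][is.na(data[[v]])] <- val
  }
  attr(data, "imputed_values") <- used
  data
}
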