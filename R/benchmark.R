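# Centre-level benchmarking: observed/expected aggregation, exact-Poisson
# funnel limits with multiplicity-adjusted significance, and Kaplan-Meier
# survival for the report headline.

#' Aggregate expected events per centre
#'
#' Sums observed deaths (O) and expected deaths (E) per centre and
#' rescales E to patient units: the effective sample size is
#' `n_eff = E / p_bar`, with `p_bar` the mean expected death probability
#' over all benchmarked patients of the transplant type - the funnel's
#' precision axis after case-mix and follow-up adjustment. Centres with
#' E = 0 are excluded with a warning. O/E is reported as 0 when O = 0.
#'
#' @param expected Data frame from [expected_probability()] (column
#'   `p_expected`).
#' @param observed Logical per-patient death-within-horizon indicators.
#' @param center Centre code per patient.
#' @return Data frame of class `"center_benchmarks"`: `center_code`, `n`,
#'   `O`, `E`, `oe_ratio`, `n_eff`; attribute `p_bar`.
#' @export
aggregate_centers <- function(expected, observed, center) {
  stopifnot(nrow(expected) == length(observed),
            length(observed) == length(center))
  p_bar <- sum(expected$p_expected) / length(observed)
  out <- do.call(rbind, lapply(split(seq_along(center), center), function(i) {
    data.frame(center_code = center[i[1]], n = length(i),
               O = sum(observed[i]), E = sum(expected$p_expected[i]),
               stringsAsFactors = FALSE)
  }))
  drop0 <- out$E == 0
  if (any(drop0)) {
    warning("centre(s) with zero expected events excluded: ",
            paste(out$center_code[drop0], collapse = ", "), call. = FALSE)
    out <- out[!drop0, , drop = FALSE]
  }
  out$oe_ratio <- ifelse(out$O == 0, 0, out$O / out$E)
  out$n_eff <- out$E / p_bar
  rownames(out) <- NULL
  structure(out, p_bar = p_bar, class = c("center_benchmarks", "data.frame"))
}

# Smooth exact-Poisson funnel limits via the gamma inversion of the
# Poisson tail: P(Pois(E) >= k) = pgamma(E, k) and
# P(Pois(E) <= k) = pgamma(E, k + 1, lower = FALSE). Solving in a
# continuous k gives limits that are monotone in E (integer-valued exact
# limits would be sawtoothed).
.poisson_upper_limit <- function(E, tail_prob) {
  vapply(E, function(e) {
    f <- function(k) stats::pgamma(e, shape = k) - tail_prob
    hi <- e + 10 * sqrt(e) + 20
    stats::uniroot(f, c(1e-9, hi), tol = 1e-9)$root / e
  }, numeric(1))
}

.poisson_lower_limit <- function(E, tail_prob) {
  vapply(E, function(e) {
    f <- function(k) stats::pgamma(e, shape = k + 1, lower.tail = FALSE) -
      tail_prob
    if (f(0) >= 0) return(0)  # even O = 0 is not below the limit
    hi <- e + 10 * sqrt(e) + 20
    stats::uniroot(f, c(0, hi), tol = 1e-9)$root / e
  }, numeric(1))
}

#' Flag centres against funnel limits
#'
#' Tests each centre's observed deaths O against its expected deaths E
#' with an exact Poisson test: upper tail `P(Pois(E) >= O)`, lower tail
#' `P(Pois(E) <= O)`. The outer (flagging) significance level is
#' multiplicity-adjusted over the K benchmarked centres (Bonferroni by
#' default, `alpha / K`); a centre is `worse_than_average` when its upper
#' tail falls below half the adjusted level, `better_than_average` for
#' the lower tail, `within` otherwise. The returned funnel curve carries
#' inner (nominal) and outer (adjusted) O/E limits on an effective-sample
#' -size grid.
#'
#' @param benchmarks An [aggregate_centers()] result.
#' @param alpha Nominal two-sided significance level (default 0.05).
#' @param adjust Multiplicity rule: `"bonferroni"` (default), `"BH"` or
#'   `"none"`.
#' @param grid_points Number of grid points for the funnel curve.
#' @return A list of class `"funnel_benchmark"`: flagged `benchmarks`
#'   (with `p_upper`, `p_lower`, `flag`), the `funnel` grid data frame,
#'   `alpha`, `alpha_adjusted`, `K` and `p_bar`.
#' @export
funnel_flags <- function(benchmarks, alpha = 0.05,
                         adjust = c("bonferroni", "BH", "none"),
                         grid_points = 100L) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  b <- as.data.frame(benchmarks)
  K <- nrow(b)
  stopifnot(K >= 1)
  p_bar <- attr(benchmarks, "p_bar")

  b$p_upper <- stats::ppois(b$O - 1, b$E, lower.tail = FALSE)
  b$p_lower <- stats::ppois(b$O, b$E)
  alpha_adj <- switch(adjust,
                      bonferroni = alpha / K,
                      none = alpha,
                      BH = {
                        two <- pmin(1, 2 * pmin(b$p_upper, b$p_lower))
                        crit <- which(sort(two) <= alpha * seq_len(K) / K)
                        if (length(crit)) sort(two)[max(crit)] else 0
                      })
  b$flag <- "within"
  b$flag[b$p_upper < alpha_adj / 2] <- "worse_than_average"
  b$flag[b$p_lower < alpha_adj / 2] <- "better_than_average"

  grid_neff <- exp(seq(log(max(min(b$n_eff), 1e-3)), log(max(b$n_eff)),
                       length.out = grid_points))
  grid_E <- grid_neff * p_bar
  funnel <- data.frame(
    n_eff = grid_neff, E = grid_E,
    inner_lower = .poisson_lower_limit(grid_E, alpha / 2),
    inner_upper = .poisson_upper_limit(grid_E, alpha / 2),
    outer_lower = if (alpha_adj > 0)
      .poisson_lower_limit(grid_E, alpha_adj / 2) else 0,
    outer_upper = if (alpha_adj > 0)
      .poisson_upper_limit(grid_E, alpha_adj / 2) else Inf)

  structure(list(benchmarks = b, funnel = funnel, alpha = alpha,
                 alpha_adjusted = alpha_adj, adjust = adjust, K = K,
                 p_bar = p_bar),
            class = "funnel_benchmark")
}

#' @export
print.funnel_benchmark <- function(x, ...) {
  cat(sprintf("Funnel benchmark: %d centre(s), alpha %.3f (adjusted %.2g, %s)\n",
              x$K, x$alpha, x$alpha_adjusted, x$adjust))
  tab <- table(factor(x$benchmarks$flag,
                      levels = c("within", "worse_than_average",
                                 "better_than_average")))
  cat(sprintf("  within: %d, worse: %d, better: %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Plot a funnel benchmark
#'
#' Scatter of O/E against effective sample size with inner (nominal) and
#' outer (multiplicity-adjusted) exact-Poisson limits; flagged centres are
#' drawn filled, and one centre can be highlighted.
#'
#' @param x A [funnel_flags()] result.
#' @param highlight Optional centre code to mark.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.funnel_benchmark <- function(x, highlight = NULL, ...) {
  b <- x$benchmarks
  f <- x$funnel
  ylim <- range(0, b$oe_ratio, f$inner_upper, na.rm = TRUE)
  graphics::plot(b$n_eff, b$oe_ratio, xlab = "Effective sample size",
                 ylab = "Observed / expected 1-year mortality",
                 ylim = ylim, pch = ifelse(b$flag == "within", 1, 16), ...)
  graphics::abline(h = 1, col = "grey60")
  graphics::lines(f$n_eff, f$inner_lower, lty = 2, col = "grey40")
  graphics::lines(f$n_eff, f$inner_upper, lty = 2, col = "grey40")
  graphics::lines(f$n_eff, f$outer_lower, lty = 1, col = "grey20")
  graphics::lines(f$n_eff, f$outer_upper, lty = 1, col = "grey20")
  if (!is.null(highlight)) {
    i <- b$center_code == highlight
    graphics::points(b$n_eff[i], b$oe_ratio[i], pch = 8, cex = 1.6,
                     col = "red3")
  }
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Thin wrapper around [survival::survfit()] returning the step function,
#' Greenwood standard errors and the horizon-day survival headline.
#'
#' @param times Non-negative follow-up days.
#' @param events Logical/0-1 death indicators.
#' @param horizon_days Day at which the headline survival is read
#'   (default 365).
#' @return A list of class `"km_curve"`: `time`, `surv`, `std_err`
#'   (Greenwood SE of S), `fun` (step function), `s_horizon`,
#'   `se_horizon`, `n`, `events`.
#' @export
kaplan_meier <- function(times, events, horizon_days = 365L) {
  if (length(times) == 0) stop("empty input")
  sf <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1,
                          conf.type = "log")
  sm <- summary(sf, times = sf$time, extend = TRUE)
  at <- summary(sf, times = min(horizon_days, max(times)), extend = TRUE)
  structure(list(time = sm$time, surv = sm$surv, std_err = sm$std.err,
                 fun = stats::stepfun(sm$time, c(1, sm$surv), right = FALSE),
                 s_horizon = at$surv, se_horizon = at$std.err,
                 n = length(times), events = sum(as.logical(events))),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: n = %d, events = %d, S(horizon) = %.3f (SE %.3f)\n",
              x$n, x$events, x$s_horizon, x$se_horizon))
  invisible(x)
}
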