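# Pipeline orchestration: eligibility -> scores -> MICE -> case-mix fit ->
# single-value imputation -> expected events -> funnel flags -> reports.

#' Run the full benchmarking pipeline for one transplant type
#'
#' Executes validation, patient and centre selection, the follow-up gate,
#' risk scoring, chained-equation imputation, the pooled case-mix fit,
#' single-value imputation among 12-month survivors, expected-event
#' computation, centre aggregation and funnel flagging. Centres failing
#' the follow-up gate stay in the completeness summaries but never enter
#' outcome benchmarking. Autologous and allogeneic pipelines are fully
#' independent: records of the other type are dropped before any
#' computation. Deterministic given `seed`.
#'
#' @param patients Patient data frame (e.g. from [read_registry()] or
#'   [generate_registry()]).
#' @param activity Activity data frame.
#' @param window An [analysis_window()].
#' @param type `"allogeneic"` or `"autologous"`.
#' @param formula Case-mix covariate formula over [casemix_frame()]
#'   columns; default from the packaged `model.yaml`.
#' @param criteria See [benchmark_criteria()].
#' @param m,iterations Chained-equation settings (defaults 5 and 10).
#' @param alpha,adjust Funnel significance level and multiplicity rule.
#' @param seed Integer seed for the imputation draws.
#' @return An object of class `"hsct_benchmark"`; see Details for the
#'   components. Use [write_bundle()] to render the artifact bundle.
#' @details Components: `rejections`, `patient_exclusions`,
#'   `center_decisions`, `followup` (with traffic lights), `fit`
#'   (a `"casemix_fit"`), `expected` (per-patient tau/lp/p), `funnel`
#'   (a `"funnel_benchmark"`), `completeness`, `dri_breakdown`,
#'   `km_overall`, `km_centers`, plus the settings used.
#' @export
run_benchmark <- function(patients, activity, window,
                          type = c("allogeneic", "autologous"),
                          formula = NULL,
                          criteria = benchmark_criteria(),
                          m = NULL, iterations = NULL,
                          alpha = NULL, adjust = NULL, seed = 1L) {
  type <- match.arg(type)
  model_cfg <- .read_config("model.yaml")
  if (is.null(formula))
    formula <- stats::reformulate(model_cfg$covariates)
  if (is.null(m)) m <- model_cfg$imputation$m
  if (is.null(iterations)) iterations <- model_cfg$imputation$iterations
  if (is.null(alpha)) alpha <- model_cfg$funnel$alpha
  if (is.null(adjust)) adjust <- model_cfg$funnel$adjust

  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  v <- step("validate", validate_patients(patients))
  pts <- v$patients[v$patients$transplant_type == type, , drop = FALSE]
  sel <- step("select_patients", select_patients(pts, window, criteria))
  pts <- sel$included
  cdec <- step("select_centers",
               select_centers(pts, activity, window, type, criteria))
  in_centers <- cdec$center_code[cdec$included]
  pts <- pts[pts$center_code %in% in_centers, , drop = FALSE]
  if (nrow(pts) == 0) stop("[select_centers] no eligible centres remain")

  fu <- step("assess_followup",
             assess_followup_by_center(pts, window, criteria))
  fu$benchmarked <- fu$ratio > criteria$followup_gate
  bench_centers <- fu$center_code[fu$benchmarked]

  dri <- step("score_dri", score_dri(pts))
  hctci <- step("score_hct_ci", score_hct_ci(pts))
  completeness <- step("completeness",
                       completeness_by_year(pts, dri, hctci))
  dri_breakdown <- dri_missingness_breakdown(pts, dri)

  cohort_mask <- pts$center_code %in% bench_centers
  cohort <- pts[cohort_mask, , drop = FALSE]
  if (nrow(cohort) == 0) stop("[assess_followup] no centre passes the follow-up gate")
  frame <- casemix_frame(cohort, dri[cohort_mask, , drop = FALSE],
                         hctci[cohort_mask, , drop = FALSE])

  model_vars <- all.vars(formula)
  mice_vars <- model_vars[vapply(frame[model_vars], anyNA, logical(1))]
  imp <- step("mice_impute",
              mice_impute(frame, mice_vars, frame$time_days, frame$event,
                          predictors = model_vars,
                          m = m, iterations = iterations, seed = seed,
                          horizon_days = window$horizon_days))
  fit <- step("fit_casemix",
              fit_casemix(formula, imp, frame$time_days, frame$event,
                          horizon_days = window$horizon_days))

  survivors <- frame$time_days >= window$horizon_days &
    !(frame$event & frame$time_days <= window$horizon_days)
  sv <- step("single_value_impute",
             single_value_impute(frame, survivors, mice_vars))
  tau <- .eval_tau(frame$time_days, frame$event, window$horizon_days)
  expected <- step("expected_probability",
                   expected_probability(fit, sv, tau))
  expected <- cbind(frame[c("patient_id", "center_code")], expected)
  observed <- frame$event & frame$time_days <= window$horizon_days
  expected$observed <- observed

  bench <- step("aggregate_centers",
                aggregate_centers(expected, observed, frame$center_code))
  funnel <- step("funnel_flags",
                 funnel_flags(bench, alpha = alpha, adjust = adjust))

  km_overall <- kaplan_meier(frame$time_days, frame$event,
                             window$horizon_days)
  km_centers <- do.call(rbind, lapply(split(frame, frame$center_code),
                                      function(f) {
    km <- kaplan_meier(f$time_days, f$event, window$horizon_days)
    data.frame(center_code = f$center_code[1], n = km$n, events = km$events,
               s_horizon = km$s_horizon, se_horizon = km$se_horizon,
               stringsAsFactors = FALSE)
  }))
  rownames(km_centers) <- NULL

  structure(list(type = type, window = window, seed = seed,
                 formula = formula, m = m, iterations = iterations,
                 alpha = alpha, adjust = adjust,
                 n_input = nrow(patients),
                 rejections = v$rejections,
                 patient_exclusions = sel$excluded,
                 center_decisions = cdec, followup = fu,
                 completeness = completeness,
                 dri_breakdown = dri_breakdown,
                 fit = fit, expected = expected,
                 funnel = funnel, km_overall = km_overall,
                 km_centers = km_centers),
            class = "hsct_benchmark")
}

#' @export
print.hsct_benchmark <- function(x, ...) {
  cat(sprintf("HSCT benchmark (%s), window %s..%s\n", x$type,
              x$window$start, x$window$end))
  cat(sprintf("  %d input records; %d centre(s) selected, %d benchmarked\n",
              x$n_input, sum(x$center_decisions$included),
              sum(x$followup$benchmarked)))
  cat(sprintf("  cohort n = %d, deaths O = %d, expected E = %.1f, O/E = %.3f\n",
              x$fit$n, sum(x$expected$observed),
              sum(x$expected$p_expected),
              sum(x$expected$observed) / sum(x$expected$p_expected)))
  cat(sprintf("  1-year survival %.1f%%; flags: %d worse, %d better of %d\n",
              100 * x$km_overall$s_horizon,
              sum(x$funnel$benchmarks$flag == "worse_than_average"),
              sum(x$funnel$benchmarks$flag == "better_than_average"),
              x$funnel$K))
  invisible(x)
}

#' @export
summary.hsct_benchmark <- function(object, ...) {
  list(type = object$type,
       centers = object$funnel$benchmarks,
       casemix = summary(object$fit),
       followup = object$followup,
       completeness = object$completeness)
}

#' @export
plot.hsct_benchmark <- function(x, highlight = NULL, ...) {
  plot(x$funnel, highlight = highlight,
       main = sprintf("1-year mortality funnel (%s)", x$type), ...)
}

.html_table <- function(df, digits = 3) {
  fmt <- function(v) {
    if (is.numeric(v)) v <- round(v, digits)
    as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  rows <- apply(cells, 1, function(r)
    paste0("<tr><td>", paste(r, collapse = "</td><td>"), "</td></tr>"))
  paste0("<table border='1' cellpadding='4' cellspacing='0'>\n<tr><th>",
         paste(names(df), collapse = "</th><th>"),
         "</th></tr>\n", paste(rows, collapse = "\n"), "\n</table>")
}

#' Write the artifact bundle of a benchmark run
#'
#' Emits the machine-readable bundle (benchmarks.csv, funnel.csv,
#' completeness.csv, exclusions.csv, followup.csv, casemix_fit.csv,
#' baseline_hazard.csv, run_manifest.json) plus one HTML report per
#' selected centre: benchmarked centres receive their clinical-outcomes
#' assessment (O, E, O/E with the adjusted funnel interval, Kaplan-Meier
#' survival), centres failing the follow-up gate receive a
#' completeness-only report. Every number in the HTML also exists in the
#' CSV/JSON bundle.
#'
#' @param x An [run_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(x, dir) {
  stopifnot(inherits(x, "hsct_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(x$funnel$benchmarks, "benchmarks.csv")
  w(x$funnel$funnel, "funnel.csv")
  w(x$completeness, "completeness.csv")
  w(x$dri_breakdown, "dri_breakdown.csv")
  w(rbind(data.frame(subject = x$patient_exclusions$patient_id,
                     reasons = x$patient_exclusions$reasons),
          data.frame(subject = x$center_decisions$center_code[!x$center_decisions$included],
                     reasons = x$center_decisions$reasons[!x$center_decisions$included])),
    "exclusions.csv")
  w(x$followup, "followup.csv")
  w(summary(x$fit)$table, "casemix_fit.csv")
  w(x$fit$basehaz, "baseline_hazard.csv")
  w(x$km_centers, "km_centers.csv")
  jsonlite::write_json(
    list(type = x$type,
         window = list(start = as.character(x$window$start),
                       end = as.character(x$window$end),
                       extraction = as.character(x$window$extraction),
                       horizon_days = x$window$horizon_days),
         seed = x$seed, m = x$m, iterations = x$iterations,
         alpha = x$alpha, adjust = x$adjust,
         covariates = all.vars(x$formula),
         package_version = as.character(utils::packageVersion("hsctbench"))),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  for (cc in x$followup$center_code) {
    fu <- x$followup[x$followup$center_code == cc, , drop = FALSE]
    parts <- c(
      sprintf("<html><head><title>Centre %s</title></head><body>", cc),
      sprintf("<h1>Benchmarking report - centre %s (%s)</h1>", cc, x$type),
      sprintf("<p>Observation window %s to %s, extraction %s.</p>",
              x$window$start, x$window$end, x$window$extraction),
      "<h2>Follow-up completeness</h2>",
      .html_table(fu[c("center_code", "n", "observed_fu_days",
                       "potential_fu_days", "ratio", "traffic_light")]),
      "<h2>Cohort data completeness by year</h2>",
      .html_table(x$completeness))
    if (fu$benchmarked) {
      b <- x$funnel$benchmarks
      b <- b[b$center_code == cc, , drop = FALSE]
      km <- x$km_centers[x$km_centers$center_code == cc, , drop = FALSE]
      if (nrow(b)) {
        lo <- .poisson_lower_limit(b$E, x$funnel$alpha_adjusted / 2)
        hi <- .poisson_upper_limit(b$E, x$funnel$alpha_adjusted / 2)
        parts <- c(parts, "<h2>Clinical outcomes</h2>",
                   .html_table(cbind(b, oe_outer_lower = lo,
                                     oe_outer_upper = hi)),
                   "<h2>One-year survival (Kaplan-Meier)</h2>",
                   .html_table(km))
      }
    } else {
      parts <- c(parts,
                 "<p>This centre did not meet the follow-up threshold;",
                 "clinical outcomes are not assessed in this report.</p>")
    }
    parts <- c(parts, "</body></html>")
    writeLines(parts, file.path(dir, sprintf("report_%s.html", cc)))
  }
  invisible(dir)
}

.cli_usage <- function() {
  paste(
    "usage: hsctbench <command> [options]",
    "",
    "commands:",
    "  simulate   --out DIR [--seed N] [--type allogeneic|autologous] [--centers N]",
    "  score      --patients FILE --out FILE",
    "  select     --patients FILE --activity FILE --out FILE [--type T]",
    "  benchmark  --patients FILE --activity FILE --out DIR [--type T] [--seed N]",
    "             [--m N] [--iterations N]",
    "",
    "common options: --start, --end, --extraction (analysis window dates)",
    sep = "\n")
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

#' Command-line entry point
#'
#' Thin argv-style interface over the package functions, used by the
#' `inst/scripts/hsctbench` wrapper: `simulate` writes a synthetic
#' registry bundle, `score` computes the risk indices for a patient CSV,
#' `select` writes the eligibility decisions, and `benchmark` runs the
#' full pipeline and writes the artifact bundle including per-centre
#' reports.
#'
#' @param args Character vector of arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 on success, 1 on error (the
#'   message names the failing stage or path).
#' @export
benchmark_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("--help", "-h", "help")) {
    cat(.cli_usage(), "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  status <- tryCatch({
    opts <- .cli_opts(args[-1])
    win <- analysis_window(
      if (is.null(opts$start)) "2015-01-01" else opts$start,
      if (is.null(opts$end)) "2019-12-31" else opts$end,
      if (is.null(opts$extraction)) "2021-05-14" else opts$extraction)
    need <- function(key) {
      if (is.null(opts[[key]])) stop("missing required option --", key)
      opts[[key]]
    }
    infile <- function(key) {
      p <- need(key)
      if (!file.exists(p)) stop("file not found: ", p)
      p
    }
    seed <- if (is.null(opts$seed)) 1L else as.integer(opts$seed)
    type <- if (is.null(opts$type)) "allogeneic" else opts$type
    switch(cmd,
      simulate = {
        out <- need("out")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        ncent <- if (is.null(opts$centers)) 50L else as.integer(opts$centers)
        reg <- generate_registry(sim_config(n_centers = ncent,
                                            transplant_type = type,
                                            window = win), seed = seed)
        write_registry(reg$patients, file.path(out, "patients.csv"))
        write_activity(reg$activity, file.path(out, "activity.csv"))
        utils::write.csv(reg$truth, file.path(out, "truth.csv"),
                         row.names = FALSE)
        message("wrote synthetic registry to ", out)
      },
      score = {
        pts <- read_registry(infile("patients"))
        out <- cbind(score_dri(pts),
                     score_hct_ci(pts)[c("hctci_score", "hctci_band",
                                         "hctci_derivation")])
        utils::write.csv(out, need("out"), row.names = FALSE)
      },
      select = {
        pts <- read_registry(infile("patients"))
        act <- read_activity(infile("activity"))
        sel <- select_patients(pts, win)
        cdec <- select_centers(sel$included, act, win, type)
        utils::write.csv(cdec, need("out"), row.names = FALSE)
      },
      benchmark = {
        pts <- read_registry(infile("patients"))
        act <- read_activity(infile("activity"))
        run <- run_benchmark(pts, act, win, type, seed = seed,
                             m = if (is.null(opts$m)) NULL
                                 else as.integer(opts$m),
                             iterations = if (is.null(opts$iterations)) NULL
                                          else as.integer(opts$iterations))
        write_bundle(run, need("out"))
        print(run)
      },
      stop("unknown command: ", cmd))
    0L
  }, error = function(e) {
    message("hsctbench ", cmd, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}
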