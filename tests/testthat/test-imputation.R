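# Nelson-Aalen estimator, chained-equation imputation and single-value
# imputation among 12-month survivors.

test_that("Nelson-Aalen hand computations and tie handling are exact", {
  expect_equal(nelson_aalen(100, TRUE)$fun(100), 1.0)
  na2 <- nelson_aalen(c(50, 100), c(TRUE, TRUE))
  expect_equal(na2$fun(49), 0)
  expect_equal(na2$fun(50), 0.5)
  expect_equal(na2$fun(100), 1.5)
  expect_equal(nelson_aalen(c(10, 20, 30), c(FALSE, FALSE, FALSE))$fun(30), 0)
  # ties aggregate d_i at equal times
  tie <- nelson_aalen(c(5, 5, 10), c(TRUE, TRUE, TRUE))
  expect_equal(tie$fun(5), 2 / 3)
  expect_equal(tie$fun(10), 2 / 3 + 1)
  expect_error(nelson_aalen(numeric(0), logical(0)), "empty")
})

test_that("Nelson-Aalen matches the survival-package estimator", {
  set.seed(42)
  t <- sample(1:120, 80, replace = TRUE)
  e <- as.logical(stats::rbinom(80, 1, 0.6))
  na <- nelson_aalen(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1, ctype = 1)
  expect_equal(na$fun(sf$time), sf$cumhaz, tolerance = 1e-12)
})

test_that("MICE with zero missingness returns identical copies", {
  d <- data.frame(x = rnorm(50), g = sample(c("a", "b"), 50, TRUE))
  imp <- mice_impute(d, vars = c("x", "g"), time = rep(365, 50),
                     event = rep(FALSE, 50), m = 3, iterations = 2, seed = 1)
  expect_length(imp, 3)
  for (i in 1:3) expect_identical(imp[[i]], d)
})

test_that("MICE is deterministic given the seed and completes all values", {
  set.seed(99)
  n <- 250
  d <- data.frame(x = rnorm(n), z = rnorm(n),
                  g = sample(c("low", "mid", "high"), n, TRUE))
  t <- pmin(rexp(n, 1 / 400), 500)
  e <- t < 500
  d$x[sample(n, 50)] <- NA
  d$g[sample(n, 50)] <- NA
  a <- mice_impute(d, vars = c("x", "g"), time = t, event = e,
                   predictors = c("x", "g", "z"), m = 2, iterations = 3,
                   seed = 7)
  b <- mice_impute(d, vars = c("x", "g"), time = t, event = e,
                   predictors = c("x", "g", "z"), m = 2, iterations = 3,
                   seed = 7)
  expect_identical(a, b)
  cc <- mice_impute(d, vars = c("x", "g"), time = t, event = e,
                    predictors = c("x", "g", "z"), m = 2, iterations = 3,
                    seed = 8)
  expect_false(identical(a[[1]]$x, cc[[1]]$x))
  for (tab in a) {
    expect_false(anyNA(tab$x))
    expect_true(all(tab$g %in% c("low", "mid", "high")))
    # observed entries are untouched
    obs <- !is.na(d$x)
    expect_identical(tab$x[obs], d$x[obs])
  }
})

test_that("a fully missing variable aborts with its name", {
  d <- data.frame(x = rep(NA_real_, 10), y = rnorm(10))
  expect_error(mice_impute(d, vars = c("x", "y"), time = rep(100, 10),
                           event = rep(TRUE, 10), m = 1, iterations = 1),
               "'x'")
})

test_that("single-value imputation uses survivor medians and lexicographic modes", {
  d <- data.frame(x = c(1, 2, 3, NA, 10),
                  g = c("B", "A", "B", "A", NA),
                  stringsAsFactors = FALSE)
  surv <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  out <- single_value_impute(d, surv)
  expect_equal(out$x[4], 2)       # median of survivors {1,2,3}
  expect_equal(out$g[5], "A")     # tie A:2 B:2 broken lexicographically
  expect_equal(out$x[c(1:3, 5)], d$x[c(1:3, 5)])  # observed unchanged

  d2 <- data.frame(g = c("A", "A", "B", "B", "B", NA))
  out2 <- single_value_impute(d2, rep(TRUE, 6))
  expect_equal(out2$g[6], "B")    # clear mode

  d3 <- data.frame(x = c(NA, 5))
  expect_error(single_value_impute(d3, c(TRUE, FALSE)), "'x'")
})

test_that("survivor-based imputation lowers expected events for sicker patients", {
  # MAR missingness concentrated in advanced-stage (sicker) patients:
  # replacing their case-mix by 12-month-survivor statistics must not
  # raise the cohort's expected deaths relative to the oracle data.
  cfg <- complete_sim_config(n_centers = 15, volume_meanlog = log(15),
                             missingness = list(comorbidity = c(0.12, 0.12),
                                                cytogenetics = c(0, 0),
                                                stage = c(0, 0),
                                                performance = c(0, 0),
                                                severity_boost = 4,
                                                center_range = 0))
  reg <- generate_registry(cfg, seed = 77)
  oracle <- casemix_frame(reg$patients_complete)
  fit <- fit_casemix(~ age_decade + dri_overall + hctci_band + perf10,
                     oracle, oracle$time_days, oracle$event)
  tau <- rep(365, nrow(oracle))
  E_oracle <- sum(expected_probability(fit, oracle, tau)$p_expected)

  frame <- casemix_frame(reg$patients)
  survivors <- frame$time_days >= 365 & !(frame$event & frame$time_days <= 365)
  sv <- single_value_impute(frame, survivors, "hctci_band")
  E_single <- sum(expected_probability(fit, sv, tau)$p_expected)
  expect_lte(E_single, E_oracle)
})
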