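# Patient/centre selection criteria and the follow-up traffic lights,
# including the documented boundary conventions.

test_that("patient selection applies the diagnosis, age and first-transplant rules", {
  win <- test_window()
  pts <- rbind(
    make_patients(1, patient_id = "keep"),
    make_patients(1, patient_id = "solid-allo", diagnosis = "solid_tumor"),
    make_patients(1, patient_id = "nonhaem-auto", diagnosis = "non_haem",
                  transplant_type = "autologous", donor_type = "auto"),
    make_patients(1, patient_id = "solid-auto", diagnosis = "solid_tumor",
                  transplant_type = "autologous", donor_type = "auto"),
    make_patients(1, patient_id = "child-auto", age_years = 12,
                  transplant_type = "autologous", donor_type = "auto",
                  diagnosis = "lymphoma"),
    make_patients(1, patient_id = "second-tx", transplant_number = 2L),
    make_patients(1, patient_id = "early-date",
                  transplant_date = as.Date("2014-12-31")))
  sel <- select_patients(pts, win)
  expect_equal(sel$included$patient_id, "keep")
  r <- function(id) sel$excluded$reasons[sel$excluded$patient_id == id]
  expect_equal(r("solid-allo"), "solid_tumor_allo")
  expect_equal(r("nonhaem-auto"), "non_haem_auto")
  expect_equal(r("solid-auto"), "non_haem_auto")
  expect_equal(r("child-auto"), "paediatric_auto")
  expect_equal(r("second-tx"), "not_first_transplant")
  expect_equal(r("early-date"), "outside_window")
  # decisions partition the input, and selection is idempotent
  expect_equal(nrow(sel$included) + nrow(sel$excluded), nrow(pts))
  again <- select_patients(sel$included, win)
  expect_equal(nrow(again$excluded), 0)
  # a paediatric allograft is kept (the age rule is autologous-only)
  kid_allo <- select_patients(make_patients(1, age_years = 10), win)
  expect_equal(nrow(kid_allo$included), 1)
})

test_that("a second transplant before 1 year does not censor the first", {
  win <- test_window()
  first <- make_patients(1, patient_id = "first", last_contact_days = 365L)
  second <- make_patients(1, patient_id = "second", transplant_number = 2L,
                          transplant_date = as.Date("2016-09-15"))
  sel <- select_patients(rbind(first, second), win)
  expect_equal(sel$included$patient_id, "first")
  expect_equal(sel$included$last_contact_days, 365L)  # untouched
})

test_that("centre volume thresholds are inclusive at 10 (allo) and 5 (auto)", {
  win <- test_window()
  cases <- list(list(n = 50, type = "allogeneic", ok = TRUE),   # 10.0/yr
                list(n = 45, type = "allogeneic", ok = FALSE),  #  9.0/yr
                list(n = 49, type = "allogeneic", ok = FALSE),  #  9.8/yr
                list(n = 25, type = "autologous", ok = TRUE),   #  5.0/yr
                list(n = 20, type = "autologous", ok = FALSE))  #  4.0/yr
  for (case in cases) {
    fx <- volume_fixture(case$n, case$type)
    dec <- select_centers(fx$patients, fx$activity, win, case$type)
    expect_equal(dec$included, case$ok,
                 label = sprintf("%s n=%d", case$type, case$n))
    if (!case$ok) expect_match(dec$reasons, "below_volume")
    expect_equal(dec$mean_annual_volume, case$n / 5)
  }
})

test_that("the reporting gate is strict at 0.80", {
  win <- test_window()
  # ratio 0.75 -> excluded
  fx <- volume_fixture(60, survey_total = 80)
  dec <- select_centers(fx$patients, fx$activity, win, "allogeneic")
  expect_false(dec$included)
  expect_match(dec$reasons, "under_reporting")
  # ratio exactly 0.80 -> still excluded (strict gate)
  fx <- volume_fixture(60, survey_total = 75)
  dec <- select_centers(fx$patients, fx$activity, win, "allogeneic")
  expect_false(dec$included)
  # ratio just above -> included
  fx <- volume_fixture(60, survey_total = 74)
  dec <- select_centers(fx$patients, fx$activity, win, "allogeneic")
  expect_true(dec$included)
  expect_equal(dec$reporting_ratio, 60 / 74)
})

test_that("membership and missing activity rows exclude a centre", {
  win <- test_window()
  fx <- volume_fixture(60)
  fx$activity$full_member <- FALSE
  dec <- select_centers(fx$patients, fx$activity, win, "allogeneic")
  expect_match(dec$reasons, "not_full_member")

  fx <- volume_fixture(60)
  expect_warning(
    dec <- select_centers(fx$patients, fx$activity[0, ], win, "allogeneic"),
    "no activity rows")
  expect_match(dec$reasons, "under_reporting")
})

test_that("follow-up ratios classify exactly at the documented boundaries", {
  win <- test_window()
  expected <- c("0.79" = "red", "0.8" = "amber", "0.85" = "amber",
                "0.9" = "amber", "0.91" = "green")
  for (f in c(0.79, 0.80, 0.85, 0.90, 0.91)) {
    a <- assess_followup(make_toy_center(100, f), win)
    expect_equal(a$ratio, f)
    expect_equal(a$traffic_light, unname(expected[as.character(f)]),
                 label = sprintf("ratio %.2f", f))
  }
  # outcome gate is strict: 0.80 stays out, 0.81 enters benchmarking
  gate <- benchmark_criteria()$followup_gate
  expect_false(0.80 > gate)
  expect_true(0.81 > gate)
})

test_that("the follow-up ratio is permutation- and duplication-invariant", {
  win <- test_window()
  pts <- make_toy_center(40, 0.85)
  shuffled <- pts[sample(nrow(pts)), ]
  expect_equal(assess_followup(shuffled, win)$ratio, 0.85)
  doubled <- rbind(pts, pts)
  doubled$patient_id <- sprintf("D%03d", seq_len(nrow(doubled)))
  expect_equal(assess_followup(doubled, win)$ratio, 0.85)
})

test_that("deaths count as fully observed follow-up", {
  win <- test_window()
  pts <- make_toy_center(10, 0)  # all lost at day 0
  pts$vital_status <- "dead"
  pts$death_days <- 30L
  pts$last_contact_days <- 30L
  a <- assess_followup(pts, win)
  expect_equal(a$ratio, 1.0)
  expect_equal(a$traffic_light, "green")
})
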