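# Registry reading/writing, schema dialects and row validation.

test_that("an empty file with header reads to an empty collection", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_registry(make_patients(0), f)
  got <- read_registry(f)
  expect_equal(nrow(got), 0)
  expect_equal(nrow(attr(got, "rejections")), 0)
})

test_that("a generated cohort round-trips read -> write -> read identically", {
  reg <- generate_registry(sim_config(n_centers = 3,
                                      volume_meanlog = log(4)), seed = 5)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg$patients, f1)
  got1 <- read_registry(f1)
  expect_equal(nrow(attr(got1, "rejections")), 0)
  write_registry(got1, f2)
  got2 <- read_registry(f2)
  expect_equal(as.data.frame(got1), as.data.frame(got2),
               ignore_attr = TRUE)
  expect_equal(got1$death_days, reg$patients$death_days)
  expect_equal(got1$diagnosis, reg$patients$diagnosis)
  expect_equal(as.numeric(got1$transplant_date),
               as.numeric(reg$patients$transplant_date))
})

test_that("repeated writes of the same records are byte-identical", {
  reg <- generate_registry(sim_config(n_centers = 4,
                                      volume_meanlog = log(10)), seed = 9)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg$patients, f1)
  write_registry(reg$patients, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("rows violating invariants are rejected with non-empty reasons", {
  pts <- rbind(
    make_patients(1, patient_id = "ok"),
    make_patients(1, patient_id = "dead-no-date", vital_status = "dead",
                  last_contact_days = 100L),
    make_patients(1, patient_id = "neg-tx", transplant_number = 0L),
    make_patients(1, patient_id = "ghost-death", death_days = 50L),
    make_patients(1, patient_id = "bad-com", comorbidity_any = "yes",
                  comorbidities = "halitosis"))
  v <- validate_patients(pts)
  expect_equal(nrow(v$patients) + nrow(v$rejections), nrow(pts))
  expect_equal(v$patients$patient_id, "ok")
  expect_true(all(nzchar(v$rejections$reason)))
  expect_match(v$rejections$reason[v$rejections$patient_id == "dead-no-date"],
               "death date required")
  expect_match(v$rejections$reason[v$rejections$patient_id == "bad-com"],
               "halitosis")
})

test_that("a dead patient's missing last contact is filled from the death day", {
  pts <- make_patients(1, vital_status = "dead", death_days = 200L,
                       last_contact_days = NA_integer_)
  v <- validate_patients(pts)
  expect_equal(v$patients$last_contact_days, 200L)
})

test_that("schema dialects map column names and enum spellings", {
  f <- withr::local_tempfile(fileext = ".csv")
  pts <- make_patients(2, transplant_type = "allogeneic")
  sch <- registry_schema(columns = c(transplant_type = "tx"),
                         dialects = list(transplant_type =
                                           c(allo = "allogeneic")))
  raw <- utils::read.csv({write_registry(pts, f); f},
                         colClasses = "character", check.names = FALSE)
  names(raw)[names(raw) == "transplant_type"] <- "tx"
  raw$tx <- c("allo", "HORSE")
  utils::write.csv(raw, f, row.names = FALSE)
  expect_warning(got <- read_registry(f, sch), "outside the dialect")
  expect_equal(got$transplant_type[1], "allogeneic")
  # unmapped spelling became missing, which fails the mandatory-field check
  expect_equal(nrow(attr(got, "rejections")), 1)
})

test_that("missing mandatory columns abort the read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,center_code\nA,B", f)
  expect_error(read_registry(f), "mandatory column")
  expect_error(read_registry(file.path(tempdir(), "nope.csv")),
               "cannot read")
})

test_that("the activity table round-trips and the window validates", {
  reg <- generate_registry(sim_config(n_centers = 3,
                                      volume_meanlog = log(4)), seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_activity(reg$activity, f)
  got <- read_activity(f)
  expect_equal(got$transplants_survey, reg$activity$transplants_survey)
  expect_true(all(got$full_member))

  expect_error(analysis_window("2019-01-01", "2015-01-01", "2021-05-14"),
               "start <= end")
  expect_warning(analysis_window("2015-01-01", "2019-12-31", "2020-03-01"),
                 "horizon")
})
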