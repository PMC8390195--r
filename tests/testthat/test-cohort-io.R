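test_that("a cohort round-trips through the two CSV tables field for field", {
  co <- tiny_cohort()
  bf <- withr::local_tempfile(fileext = ".csv")
  vf <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, bf, vf)
  back <- read_cohort(bf, vf)
  expect_equal(back$baselines, co$baselines)
  expect_equal(back$visits, co$visits)
  expect_identical(nrow(attr(back, "rejected")), 0L)
})

test_that("column_map lets renamed headers be ingested", {
  b <- tiny_baselines()
  names(b)[names(b) == "patient_id"] <- "ID"
  names(b)[names(b) == "nfl_at_baseline"] <- "NfL"
  v <- tiny_visits()
  names(v)[names(v) == "patient_id"] <- "ID"
  bf <- withr::local_tempfile(fileext = ".csv")
  vf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(b, bf)
  readr::write_csv(v, vf)
  co <- read_cohort(bf, vf,
                    column_map = c(patient_id = "ID", nfl_at_baseline = "NfL"))
  expect_identical(nrow(co$baselines), 2L)
  expect_identical(nrow(co$visits), 4L)
  # ... and the same map can come from a YAML config file
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("column_map:", "  patient_id: ID", "  nfl_at_baseline: NfL"),
             cfg)
  co2 <- read_cohort(bf, vf, config = cfg)
  expect_equal(co2$baselines, co$baselines)
})

test_that("a missing required column is a configuration error", {
  b <- tiny_baselines()
  b$nfl_at_baseline <- NULL
  bf <- withr::local_tempfile(fileext = ".csv")
  vf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(b, bf)
  readr::write_csv(tiny_visits(), vf)
  expect_error(read_cohort(bf, vf), "configuration.*nfl_at_baseline")
})

test_that("a visit referencing an unknown patient is a validation error naming it", {
  v <- tiny_visits()
  v$patient_id[4] <- "X9"
  bf <- withr::local_tempfile(fileext = ".csv")
  vf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tiny_baselines(), bf)
  readr::write_csv(v, vf)
  expect_error(read_cohort(bf, vf), "X9")
})

test_that("rows with invalid required fields are rejected with a reason", {
  b <- tiny_baselines()
  b$nfl_at_baseline[2] <- 0
  bf <- withr::local_tempfile(fileext = ".csv")
  vf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(b, bf)
  readr::write_csv(tiny_visits()[1:2, ], vf)
  expect_message(co <- read_cohort(bf, vf), "rejected")
  rej <- attr(co, "rejected")
  expect_identical(rej$patient_id, "B2")
  expect_identical(rej$reason, "non-positive NfL")
  expect_identical(nrow(co$baselines), 1L)
})

test_that("validate_cohort reports instead of raising", {
  expect_identical(nrow(validate_cohort(tiny_cohort())), 0L)

  b <- tiny_baselines()
  b$alsfrs_r_at_baseline[1] <- 50
  bad_score <- cohort(b, tiny_visits(), check = FALSE)
  rep1 <- validate_cohort(bad_score)
  expect_identical(rep1$issue, "score out of range [0, 48]")
  expect_identical(rep1$patient_id, "A1")

  v <- tiny_visits()
  v$months_since_baseline[2] <- 0  # duplicates A1's visit time
  dup <- cohort(tiny_baselines(), v, check = FALSE)
  rep2 <- validate_cohort(dup)
  expect_true("duplicated time point" %in% rep2$issue)

  # inconsistent onset clock is reported, not fatal
  v2 <- tiny_visits()
  v2$months_since_onset[2] <- 20  # should be ~13
  rep3 <- validate_cohort(cohort(tiny_baselines(), v2, check = FALSE))
  expect_true("inconsistent with months_since_baseline + disease duration"
              %in% rep3$issue)
})

test_that("structural integrity is enforced at construction", {
  b <- tiny_baselines()[c(1, 1), ]
  expect_error(cohort(b, tiny_visits()), "duplicated patient id")
  v <- tiny_visits()
  v$months_since_baseline[2] <- 0
  expect_error(cohort(tiny_baselines(), v), "duplicated \\(patient, time\\)")
})
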