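two_arm_design <- function(n = 20, seed = 31, ...) {
  g <- generate_trial(synthetic_config(n_patients = n, seed = seed, ...))
  preds <- predicted_slopes(g$cohort, "nfl_model")
  build_design(g$cohort, preds, g$assignment)
}

test_that("build_design centres time at each patient's first retained visit", {
  b <- tibble::tibble(patient_id = c("A", "B"), onset_site = "spinal",
                      disease_duration_at_baseline = 10,
                      alsfrs_r_at_baseline = 44, nfl_at_baseline = 100)
  v <- expand.grid(patient_id = c("A", "B"),
                   months_since_baseline = c(0, 3, 6, 9),
                   stringsAsFactors = FALSE)
  v$alsfrs_r <- 44 - v$months_since_baseline
  co <- cohort(b, v)
  d <- build_design(co, c(A = -1, B = -1), c(A = 0, B = 1))
  expect_identical(nrow(d), 6L)
  expect_equal(sort(unique(d$t)), c(0, 3, 6))
  expect_true(all(d$a1 == 41))              # score at the month-3 boundary
  expect_true(all(d$t == 0 | d$a < d$a1 + 1))
  expect_equal(unique(d$treatment[d$patient_id == "B"]), 1)
})

test_that("patients without enough interventional visits or assignment are excluded", {
  b <- tibble::tibble(patient_id = c("A", "B", "C"), onset_site = "spinal",
                      disease_duration_at_baseline = 10,
                      alsfrs_r_at_baseline = 44, nfl_at_baseline = 100)
  v <- tibble::tibble(
    patient_id = c(rep("A", 4), rep("B", 4), "C", "C"),
    months_since_baseline = c(0, 3, 6, 9, 0, 3, 6, 9, 0, 3),
    alsfrs_r = 40)
  co <- cohort(b, v)
  d <- build_design(co, c(A = -1, B = -0.5, C = -2), c(A = 0, B = 1, C = 1))
  expect_false("C" %in% d$patient_id)       # one interventional visit only
  excl <- attr(d, "excluded")
  expect_true("C" %in% excl$patient_id)
  expect_error(build_design(co, c(A = -1, B = -0.5), c(A = 1, B = 1)),
               "single-arm")
})

test_that("saving_percent follows the SE-shrinkage formula and is monotone", {
  expect_equal(saving_percent(1, 1), 0)
  expect_equal(saving_percent(1 / sqrt(2), 1), 50)
  expect_equal(saving_percent(0.5, 1), 75)
  expect_error(saving_percent(0, 1), "positive")
  withr::with_seed(77, {
    se_null <- runif(200, 0.1, 2)
    a1 <- runif(200, 0.05, 3)
    a2 <- a1 + runif(200, 0.001, 1)
    expect_true(all(saving_percent(a1, se_null) >
                      saving_percent(a2, se_null)))
  })
})

test_that("constant predictions degrade gracefully to the null model", {
  d <- two_arm_design()
  d$p <- -0.75
  expect_warning(fits <- fit_power_models(d), "constant")
  expect_equal(fits$alt$se_beta2, fits$null$se_beta2)
  expect_equal(saving_percent(fits$alt$se_beta2, fits$null$se_beta2), 0)
})

test_that("flipping the arm labels flips beta2 but not its standard error", {
  d <- two_arm_design(n = 24, seed = 33)
  f1 <- fit_power_models(d)
  d2 <- d
  d2$treatment <- 1 - d2$treatment
  f2 <- fit_power_models(d2)
  b2 <- function(f) unname(f$alt$coefficients["t:treatment"])
  expect_equal(b2(f2), -b2(f1), tolerance = 1e-5)
  expect_equal(f2$alt$se_beta2, f1$alt$se_beta2, tolerance = 1e-5)
  expect_equal(f2$null$se_beta2, f1$null$se_beta2, tolerance = 1e-5)
})

test_that("the mixed model recovers a simulated treatment effect", {
  g <- generate_trial(synthetic_config(n_patients = 200,
                                       treatment_effect = 0.3, seed = 35))
  d <- build_design(g$cohort, predicted_slopes(g$cohort, "nfl_model"),
                    g$assignment)
  f <- fit_power_models(d)
  expect_true(f$alt$converged && f$null$converged)
  b2 <- unname(f$alt$coefficients["t:treatment"])
  expect_lt(abs(b2 - 0.3), 3 * f$alt$se_beta2)
  expect_gt(f$alt$random_slope_sd, 0)
})

test_that("permutation streams are reproducible bit for bit", {
  g <- generate_cohort(synthetic_config(n_patients = 16, seed = 40))
  preds <- predicted_slopes(g$cohort, "nfl_model")
  p1 <- permutation_power(g$cohort, preds, n_perm = 8, seed = 123)
  p2 <- permutation_power(g$cohort, preds, n_perm = 8, seed = 123)
  expect_identical(p1$savings, p2$savings)
  expect_identical(p1$central_median, p2$central_median)
  p3 <- permutation_power(g$cohort, preds, n_perm = 8, seed = 124)
  expect_false(identical(p1$savings, p3$savings))
  expect_true(p1$ci_low <= p1$central_median &&
                p1$central_median <= p1$ci_high)
})

test_that("more informative predictors never lower the median saving", {
  g <- generate_cohort(synthetic_config(n_patients = 46,
                                        slope_noise_sd = 0.6,
                                        score_noise_sd = 0.5, seed = 44))
  oracle <- tibble::tibble(patient_id = g$truth$patient_id,
                           p = g$truth$true_slope)
  noisy <- oracle
  noisy$p <- noisy$p + withr::with_seed(45, rnorm(46, 0, 0.6))
  pure <- oracle
  pure$p <- withr::with_seed(46, rnorm(46, -0.75, 0.6))
  m <- vapply(list(oracle, noisy, pure), function(pr) {
    permutation_power(g$cohort, pr, n_perm = 30, seed = 99)$central_median
  }, numeric(1))
  expect_gte(m[1], m[2])
  expect_gte(m[2], m[3])
})
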