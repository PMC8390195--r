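test_that("the published model reproduces its worked examples", {
  expect_equal(round(predict_slope(100, "spinal"), 2), -0.75)
  expect_equal(round(predict_slope(100, "bulbar"), 2), -0.75)
  expect_equal(predict_slope(1, "bulbar"), 4.45)  # ln(1) = 0
  expect_error(predict_slope(0, "spinal"), "positive")
  expect_error(predict_slope(100, "lumbar"), "spinal")
})

test_that("predictions decrease in NfL for both sites, bulbar more steeply", {
  nfl <- exp(seq(2, 7, by = 0.25))
  for (site in c("spinal", "bulbar")) {
    expect_true(all(diff(predict_slope(nfl, site)) < 0))
  }
  d_sp <- diff(predict_slope(c(50, 500), "spinal"))
  d_bu <- diff(predict_slope(c(50, 500), "bulbar"))
  expect_lt(d_bu, d_sp)  # both negative; bulbar drops further
})

test_that("ln(NfL) sensitivity matches the published values", {
  expect_equal(round(ln_nfl_sensitivity(0.5, "spinal"), 2), 1.67)
  expect_equal(round(ln_nfl_sensitivity(0.5, "bulbar"), 2), 0.44)
  expect_equal(ln_nfl_sensitivity(0, "spinal"), 0)
  flat_spinal <- nfl_coefficients(1, -0.83, -2, 0.83)  # spinal branch flat
  expect_error(ln_nfl_sensitivity(0.5, "spinal", flat_spinal), "undefined")
  expect_equal(ln_nfl_sensitivity(0.5, "bulbar", flat_spinal), 0.5 / 0.83)
})

test_that("the crossover concentration equalizes the two branches", {
  x <- crossover_nfl()
  expect_equal(round(x, 1), 99.7)            # exp(3.82 / 0.83)
  expect_equal(signif(x, 2), 100)
  expect_equal(predict_slope(x, "spinal"), predict_slope(x, "bulbar"))
  expect_equal(crossover_nfl(nfl_coefficients(1, -1, 0, -0.8)), 1)
  expect_error(crossover_nfl(nfl_coefficients(1, -1, -2, 0)), "never cross")
  expect_warning(x0 <- crossover_nfl(nfl_coefficients(1, -1, 0, 0)),
                 "everywhere")
  expect_true(is.na(x0))
})

syn_candidates <- c("ln_nfl", "onset_site", "disease_duration", "delta_frs",
                    "alsfrs_r_at_baseline", "ln_nfl:onset_site")

dev_data <- function(g, outcome = g$truth$true_slope) {
  dplyr::inner_join(
    tibble::tibble(patient_id = g$truth$patient_id, slope = outcome),
    candidate_predictors(g$cohort), by = "patient_id")
}

test_that("a noise-free cohort is perfectly identifiable", {
  cfg <- synthetic_config(n_patients = 50, slope_noise_sd = 0,
                          score_noise_sd = 0, nfl_rel_fluct_sd = 0, seed = 7)
  g <- generate_cohort(cfg)
  s <- cohort_slopes(g$cohort)
  pred <- predict_slope(g$cohort$baselines$nfl_at_baseline,
                        g$cohort$baselines$onset_site)
  expect_lt(max(abs(s$slope - pred)), 1e-9)
  # zero residuals make summary.lm warn about a perfect fit, by design here
  fit <- suppressWarnings(develop_model(dev_data(g, s$slope),
                                        candidates = c("ln_nfl", "onset_site",
                                                       "ln_nfl:onset_site"),
                                        all_subsets = FALSE))
  est <- fit$estimates
  expect_lt(max(abs(est - c(4.45, -1.13, -3.82, 0.83))), 1e-6)
})

test_that("development retains the NfL terms in most seeded replicates", {
  hits <- vapply(1:10, function(s) {
    g <- generate_cohort(synthetic_config(n_patients = 200, seed = s))
    fit <- suppressMessages(develop_model(dev_data(g),
                                          candidates = syn_candidates,
                                          all_subsets = FALSE))
    setequal(fit$terms, c("ln_nfl", "onset_site", "ln_nfl:onset_site"))
  }, logical(1))
  expect_gte(sum(hits), 6)
})

test_that("a pure-noise outcome is eliminated down to the intercept", {
  n_ret <- vapply(1:30, function(s) {
    g <- generate_cohort(synthetic_config(n_patients = 200, seed = s))
    noise <- withr::with_seed(1000 + s, rnorm(200))
    fit <- suppressMessages(develop_model(dev_data(g, noise),
                                          candidates = syn_candidates,
                                          all_subsets = FALSE))
    length(fit$terms)
  }, integer(1))
  expect_lt(mean(n_ret), 1)                 # per-term retention near alpha
  expect_identical(median(n_ret), 0)        # typical outcome: intercept only
})

test_that("elimination trace and hierarchy bookkeeping are coherent", {
  g <- generate_cohort(synthetic_config(n_patients = 200, seed = 2))
  fit <- suppressMessages(develop_model(dev_data(g),
                                        candidates = syn_candidates))
  expect_setequal(c(fit$terms, fit$elimination$term), syn_candidates)
  expect_true(all(fit$p_values[fit$terms] < fit$alpha))
  expect_equal(fit$r, sqrt(max(fit$adjusted_r2, 0)))
  # interaction never appears without both parents anywhere in the ranking
  with_int <- grepl("ln_nfl:onset_site", fit$subsets$terms, fixed = TRUE)
  expect_true(all(grepl("onset_site", fit$subsets$terms[with_int])))
})

test_that("subsets containing ln(NfL) outrank their ln(NfL)-free twins", {
  g <- generate_cohort(synthetic_config(n_patients = 200, seed = 11))
  fit <- suppressMessages(develop_model(dev_data(g),
                                        candidates = syn_candidates))
  ranking <- fit$subsets
  key <- function(terms) paste(sort(terms), collapse = "+")
  adj <- setNames(ranking$adjusted_r2,
                  vapply(strsplit(ranking$terms, " \\+ "), key, ""))
  base_terms <- c("disease_duration", "delta_frs", "alsfrs_r_at_baseline",
                  "onset_site")
  expect_gt(adj[["ln_nfl"]], 0)  # vs the intercept-only baseline
  for (k in 1:2) {
    for (s in combn(base_terms, k, simplify = FALSE)) {
      expect_gt(adj[[key(c(s, "ln_nfl"))]], adj[[key(s)]])
    }
  }
})

test_that("rank-deficient designs are refused with the collinear term named", {
  g <- generate_cohort(synthetic_config(n_patients = 50, seed = 3))
  d <- dev_data(g)
  d$dup <- d$ln_nfl
  expect_error(
    suppressMessages(develop_model(d, candidates = c("ln_nfl", "dup"),
                                   all_subsets = FALSE)),
    "collinear.*dup")
})

test_that("as_nfl_coefficients needs exactly the NfL-model structure", {
  g <- generate_cohort(synthetic_config(n_patients = 200, seed = 1))
  fit <- suppressMessages(develop_model(
    dev_data(g), candidates = c("ln_nfl", "onset_site", "ln_nfl:onset_site"),
    all_subsets = FALSE))
  cf <- as_nfl_coefficients(fit)
  expect_s3_class(cf, "nfl_coefficients")
  expect_equal(predict_slope(100, "spinal", cf),
               unname(fit$estimates["(Intercept)"] +
                        (fit$estimates["ln_nfl"] +
                           fit$estimates["ln_nfl:onset_site"]) * log(100) +
                        fit$estimates["onset_site"]))
  int_only <- suppressMessages(develop_model(
    dev_data(g, withr::with_seed(5, rnorm(200))),
    candidates = c("disease_duration"), all_subsets = FALSE))
  expect_error(as_nfl_coefficients(int_only), "structure")
})
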