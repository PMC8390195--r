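#' Configuration of the synthetic ALS cohort generator
#'
#' Defaults emulate the observational development cohort the NfL model was
#' built on: about 78% spinal onset, baseline ln(NfL) normal with mean 4.63
#' and SD 0.81 ln(pg/ml), baseline ALSFRS-R around 42 points, disease
#' duration log-normal with median 10.1 months, visits every 3 months up to
#' 18 months, and true per-patient slopes drawn from the published NfL
#' model plus Gaussian heterogeneity.
#'
#' @param n_patients Number of patients (default 46).
#' @param prop_spinal Probability of spinal onset (default 0.78).
#' @param ln_nfl_mean,ln_nfl_sd Baseline ln(NfL) distribution, ln(pg/ml)
#'   (defaults 4.63, 0.81).
#' @param true_coefficients [nfl_coefficients()] generating the systematic
#'   part of the true slope (default [published_nfl_coefficients]).
#' @param slope_noise_sd SD of the Gaussian slope heterogeneity around the
#'   model prediction, pt/month (default 0.45; sized so that refitting the
#'   model on generated cohorts lands near the internal-validation
#'   correlation R of about 0.67).
#' @param score_noise_sd SD of the per-visit ALSFRS-R measurement noise,
#'   points (default 1.5). When positive, observed scores are rounded and
#'   clipped to `[0, 48]`; exactly 0 produces idealized unrounded linear
#'   trajectories (used by identifiability checks).
#' @param baseline_score_mean,baseline_score_sd Baseline ALSFRS-R
#'   distribution before rounding/clipping (defaults 42, 2).
#' @param duration_median_months Median disease duration at baseline,
#'   months (default 10.1); the duration is log-normal.
#' @param duration_sdlog SD of log-duration (default 0.8, matching the
#'   spread of the development cohort's interquartile range).
#' @param visit_interval_months,followup_months Visit schedule: visits at
#'   0, interval, 2*interval, ... up to the follow-up horizon (defaults 3
#'   and 18 months).
#' @param nfl_rel_fluct_sd Within-patient fluctuation of the ln(NfL) level,
#'   as a fraction of the level (default 0.03, landing mean relative
#'   deviations near the observed 2.5--4.8% range).
#' @param treatment_effect Slope shift, in pt/month, added to treated
#'   patients by [generate_trial()] (default 0; positive = slower decline).
#' @param cohort_label Label stamped on the baseline table (default
#'   `"SYN"`).
#' @param seed Integer seed; the generators are bit-for-bit reproducible
#'   given the same config and seed, and restore the global RNG state.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 46, prop_spinal = 0.78,
                             ln_nfl_mean = 4.63, ln_nfl_sd = 0.81,
                             true_coefficients = published_nfl_coefficients,
                             slope_noise_sd = 0.45, score_noise_sd = 1.5,
                             baseline_score_mean = 42,
                             baseline_score_sd = 2,
                             duration_median_months = 10.1,
                             duration_sdlog = 0.8,
                             visit_interval_months = 3,
                             followup_months = 18,
                             nfl_rel_fluct_sd = 0.03,
                             treatment_effect = 0,
                             cohort_label = "SYN", seed = NULL) {
  stopifnot(
    n_patients >= 0,
    prop_spinal >= 0, prop_spinal <= 1,
    inherits(true_coefficients, "nfl_coefficients"),
    ln_nfl_sd >= 0, slope_noise_sd >= 0, score_noise_sd >= 0,
    baseline_score_sd >= 0, duration_sdlog >= 0, nfl_rel_fluct_sd >= 0,
    duration_median_months > 0,
    visit_interval_months > 0,
    followup_months >= visit_interval_months
  )
  structure(as.list(environment()), class = "synthetic_config")
}

.with_config_seed <- function(config, code) {
  if (is.null(config$seed)) code() else withr::with_seed(config$seed, code())
}

.generate <- function(config, assignment = NULL) {
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  site <- ifelse(rbinom(n, 1, config$prop_spinal) == 1, "spinal", "bulbar")
  ln0 <- rnorm(n, config$ln_nfl_mean, config$ln_nfl_sd)
  natural_slope <- predict_slope(exp(ln0), site, config$true_coefficients) +
    rnorm(n, 0, config$slope_noise_sd)
  score0 <- pmin(48, pmax(0, round(rnorm(n, config$baseline_score_mean,
                                         config$baseline_score_sd))))
  dur <- rlnorm(n, log(config$duration_median_months), config$duration_sdlog)

  true_slope <- natural_slope
  if (!is.null(assignment)) {
    true_slope <- natural_slope + config$treatment_effect * assignment
  }

  times <- seq(0, config$followup_months, by = config$visit_interval_months)
  k <- length(times)
  visits <- tibble::tibble(
    patient_id = rep(ids, each = k),
    months_since_baseline = rep(times, times = n),
    months_since_onset = rep(dur, each = k) + rep(times, times = n)
  )
  mu <- rep(score0, each = k) + rep(true_slope, each = k) *
    visits$months_since_baseline
  if (config$score_noise_sd > 0) {
    visits$alsfrs_r <- round(pmin(48, pmax(0, mu +
      rnorm(n * k, 0, config$score_noise_sd))))
  } else {
    # Zero measurement noise requests idealized linear trajectories
    # (no rounding or clipping), so that per-patient OLS recovers the
    # truth-table slope exactly in identifiability checks.
    visits$alsfrs_r <- mu
  }
  # t = 0 is the baseline blood draw itself; later visits fluctuate
  # multiplicatively on the ln scale.
  fluct <- rnorm(n * k, 0, config$nfl_rel_fluct_sd)
  at_baseline <- visits$months_since_baseline == 0
  fluct[at_baseline] <- 0
  visits$nfl_pg_ml <- exp(rep(ln0, each = k) * (1 + fluct))

  baselines <- tibble::tibble(
    patient_id = ids,
    cohort_label = config$cohort_label,
    onset_site = site,
    disease_duration_at_baseline = dur,
    alsfrs_r_at_baseline = score0,
    nfl_at_baseline = exp(ln0)
  )
  truth <- tibble::tibble(
    patient_id = ids,
    true_slope = true_slope,
    natural_slope = natural_slope,
    ln_nfl = ln0,
    onset_site = site
  )
  list(cohort = cohort(baselines, visits), truth = truth)
}

#' Generate a synthetic longitudinal ALS cohort
#'
#' Draws a cohort with the statistical structure the analysis assumes: per
#' patient, onset site ~ Bernoulli(`prop_spinal`); baseline ln(NfL) ~
#' Normal; true slope = NfL-model prediction + Normal(0, `slope_noise_sd`);
#' baseline score ~ rounded, clipped Normal; duration ~ log-normal; visits
#' on a fixed schedule with observed scores rounded and clipped to
#' `[0, 48]` after Gaussian measurement noise; and longitudinal ln(NfL)
#' fluctuating multiplicatively around the baseline level. Trajectories are
#' linear by construction.
#'
#' @param config A [synthetic_config()].
#' @return List with `cohort` (an `nfl_cohort`) and `truth` (tibble
#'   `patient_id`, `true_slope`, `natural_slope`, `ln_nfl`, `onset_site`):
#'   the generator's side-channel ground truth.
#' @export
#' @examples
#' g <- generate_cohort(synthetic_config(n_patients = 10, seed = 1))
#' g$cohort
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_config_seed(config, function() .generate(config))
}

#' Generate a synthetic randomized trial
#'
#' As [generate_cohort()], but patients are first randomized 1:1 to
#' treatment and control (for odd n the arm sizes differ by one, the larger
#' side chosen by a fair coin) and treated patients' true slopes are
#' shifted by `+treatment_effect` pt/month (a slowing of decline).
#'
#' @inheritParams generate_cohort
#' @return List with `cohort`, `truth` (whose `true_slope` includes the
#'   treatment shift; `natural_slope` does not) and `assignment` (tibble
#'   `patient_id`, `treatment`).
#' @export
generate_trial <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_config_seed(config, function() {
    n <- config$n_patients
    k <- n %/% 2L
    if (n %% 2L == 1L) k <- k + rbinom(1L, 1L, 0.5)
    treated_idx <- sample.int(n, k)
    assignment <- as.numeric(seq_len(n) %in% treated_idx)
    g <- .generate(config, assignment = assignment)
    g$assignment <- tibble::tibble(patient_id = g$truth$patient_id,
                                   treatment = assignment)
    g
  })
}
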