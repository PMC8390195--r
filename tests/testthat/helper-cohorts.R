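# Small deterministic fixtures, built in code.

tiny_baselines <- function() {
  tibble::tibble(
    patient_id = c("A1", "B2"),
    cohort_label = "T",
    onset_site = c("spinal", "bulbar"),
    sex = c("male", "female"),
    age_at_onset = c(60, 55),
    disease_duration_at_baseline = c(10, 12),
    alsfrs_r_at_baseline = c(42, 36),
    bmi = c(25.4, 23.1),
    nfl_at_baseline = c(100, 60),
    deceased = c(FALSE, TRUE),
    months_survived_since_onset = c(NA, 30)
  )
}

tiny_visits <- function() {
  tibble::tibble(
    patient_id = c("A1", "A1", "B2", "B2"),
    months_since_baseline = c(0, 3, 0, 6),
    months_since_onset = c(10, 13, 12, 18),
    alsfrs_r = c(42, 40, 36, 30),
    nfl_pg_ml = c(100, 104, 60, NA)
  )
}

tiny_cohort <- function() cohort(tiny_baselines(), tiny_visits())

# A cohort whose trajectories are exactly linear (integer scores), so the
# lead-in slope, interventional slope and full slope all coincide.
linear_cohort <- function(slopes_per_visit = c(-3, -2, -1),
                          lead_in_months = 3) {
  n <- length(slopes_per_visit)
  ids <- paste0("L", seq_len(n))
  b <- tibble::tibble(
    patient_id = ids, onset_site = "spinal",
    disease_duration_at_baseline = 10,
    alsfrs_r_at_baseline = 45, nfl_at_baseline = 100
  )
  v <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- seq(0, 12, by = 3)
    tibble::tibble(patient_id = ids[i], months_since_baseline = t,
                   alsfrs_r = 45 + slopes_per_visit[i] * t / 3)
  }))
  cohort(b, v)
}

# Independent normal-equations oracle for simple OLS.
ols_oracle <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}
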