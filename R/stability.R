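#' Mean relative deviation of a patient's ln(NfL) series
#'
#' Temporal stability of a patient's blood NfL, measured on the natural-log
#' scale: the mean over measurements of
#' `|ln(NfL_j) - mean_i| / mean_i * 100`, where `mean_i` is the patient's
#' mean ln(NfL).
#'
#' @param nfl_series Numeric vector of NfL concentrations in pg/ml
#'   (>= 2 values, all > 0).
#' @return Patient-level mean relative deviation in percent (>= 0).
#' @export
#' @examples
#' relative_deviation(exp(c(4.0, 4.2)))  # about 2.44 %
relative_deviation <- function(nfl_series) {
  nfl_series <- nfl_series[!is.na(nfl_series)]
  if (length(nfl_series) < 2) {
    stop("need at least 2 NfL measurements", call. = FALSE)
  }
  if (any(nfl_series <= 0)) {
    stop("NfL concentrations must be positive", call. = FALSE)
  }
  lnv <- log(nfl_series)
  m <- mean(lnv)
  if (m <= 0) {
    stop("mean ln(NfL) must be positive for a relative deviation",
         call. = FALSE)
  }
  mean(abs(lnv - m)) / m * 100
}

# Per-patient ln(NfL) measurement series: the baseline concentration
# followed by the non-missing visit concentrations at t > 0 in time order.
# A visit at exactly t = 0 is treated as the baseline draw and not
# duplicated into the series.
.nfl_series_table <- function(x) {
  b <- x$baselines
  v <- x$visits
  v <- v[!is.na(v$nfl_pg_ml) & v$months_since_baseline > 0, ]
  v <- v[order(v$patient_id, v$months_since_baseline), ]
  follow <- split(v$nfl_pg_ml, v$patient_id)
  lapply(setNames(b$patient_id, b$patient_id), function(id) {
    c(b$nfl_at_baseline[b$patient_id == id], follow[[id]])
  })
}

#' Within-patient ln(NfL) stability across a cohort
#'
#' Aggregation is per patient first: per-measurement relative deviations
#' (see [relative_deviation()]) are averaged within each patient, then the
#' mean and SD are taken across patients. Additionally the empirical 2.5
#' and 97.5 percentiles (linear interpolation between order statistics) of
#' the signed difference `ln(NfL at first follow-up) - ln(NfL at
#' baseline)` are reported. Patients with fewer than two NfL measurements
#' are skipped and listed in `attr(x, "skipped")`.
#'
#' @param x An `nfl_cohort` whose visits carry `nfl_pg_ml` for at least one
#'   patient at a time > 0.
#' @return Object of class `stability_summary`: list with
#'   `mean_rel_dev_pct`, `sd_rel_dev_pct`, `diff_p2_5`, `diff_p97_5`
#'   (ln units), `n_patients`, `n_measurements`, `per_patient` (tibble
#'   `patient_id`, `rel_dev_pct`, `first_followup_diff`) and
#'   `trajectories` (tibble `patient_id`, `measurement_index`, `ln_nfl`).
#' @export
stability_summary <- function(x) {
  stopifnot(inherits(x, "nfl_cohort"))
  series <- .nfl_series_table(x)
  lens <- lengths(series)
  eligible <- names(series)[lens >= 2]
  if (length(eligible) == 0) {
    stop("no patient has 2 or more NfL measurements", call. = FALSE)
  }
  per_patient <- tibble::tibble(
    patient_id = eligible,
    rel_dev_pct = unname(vapply(series[eligible], relative_deviation,
                                numeric(1))),
    first_followup_diff = unname(vapply(series[eligible], function(s) {
      log(s[2]) - log(s[1])
    }, numeric(1)))
  )
  traj <- dplyr::bind_rows(lapply(eligible, function(id) {
    tibble::tibble(patient_id = id,
                   measurement_index = seq_along(series[[id]]),
                   ln_nfl = log(series[[id]]))
  }))
  qs <- quantile(per_patient$first_followup_diff, c(0.025, 0.975),
                 type = 7, names = FALSE)
  out <- structure(list(
    mean_rel_dev_pct = mean(per_patient$rel_dev_pct),
    sd_rel_dev_pct = sd(per_patient$rel_dev_pct),
    diff_p2_5 = qs[1],
    diff_p97_5 = qs[2],
    n_patients = length(eligible),
    n_measurements = sum(lens[eligible]),
    per_patient = per_patient,
    trajectories = traj
  ), class = "stability_summary")
  attr(out, "skipped") <- tibble::tibble(
    patient_id = names(series)[lens < 2],
    reason = "fewer than 2 NfL measurements")
  out
}

#' @export
print.stability_summary <- function(x, ...) {
  cat("<stability_summary>  ", x$n_patients, " patients, ",
      x$n_measurements, " measurements\n", sep = "")
  cat(sprintf("  mean relative ln(NfL) deviation: %.1f%% (SD %.1f%%)\n",
              x$mean_rel_dev_pct, x$sd_rel_dev_pct))
  cat(sprintf(
    "  baseline to first follow-up difference, 2.5/97.5 percentiles: [%.2f, %.2f] ln units\n",
    x$diff_p2_5, x$diff_p97_5))
  invisible(x)
}
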