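#' Per-patient ALSFRS-R slope by ordinary least squares
#'
#' Regresses a patient's ALSFRS-R sum scores on visit times (months) and
#' returns the fitted line. Slopes are signed: negative values mean
#' functional decline.
#'
#' @param times Numeric vector of visit times in months.
#' @param scores Numeric vector of ALSFRS-R sum scores (same length).
#' @param patient_id Identifier carried into the result.
#' @param period Which follow-up window the visits came from
#'   (`"full_followup"`, `"lead_in"` or `"interventional"`); metadata only.
#' @param time_origin What `times` are measured from (`"baseline"`,
#'   `"onset"` or `"interventional_start"`); metadata only. The slope is
#'   invariant to the choice, the intercept is not.
#'
#' @return One-row tibble: `patient_id`, `slope` (pt/month), `intercept`
#'   (points), `n_points`, `period`, `time_origin`.
#' @export
#' @examples
#' fit_patient_slope(c(0, 3, 6, 9), c(44, 42, 39, 37))  # slope -0.8
fit_patient_slope <- function(times, scores, patient_id = NA_character_,
                              period = "full_followup",
                              time_origin = "baseline") {
  if (length(times) != length(scores)) {
    stop("times and scores must have equal length", call. = FALSE)
  }
  if (length(times) < 2 || dplyr::n_distinct(times) < 2) {
    stop("insufficient data for patient '", patient_id,
         "': need >= 2 visits at distinct times", call. = FALSE)
  }
  fit <- lm(scores ~ times)
  tibble::tibble(
    patient_id = as.character(patient_id),
    slope = unname(coef(fit)[["times"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    n_points = length(times),
    period = period,
    time_origin = time_origin
  )
}

#' Monthly ALSFRS-R decrease since disease onset (delta-FRS)
#'
#' The historical progression proxy: points lost from the maximal score of
#' 48 divided by the months between symptom onset and baseline. Stored
#' positive (a decline *rate*); negate it when using it as a prediction of
#' a signed slope.
#'
#' @param alsfrs_r_at_baseline ALSFRS-R sum score at baseline (0--48).
#' @param disease_duration_at_baseline Months between onset and baseline
#'   (> 0). Vectors are recycled against each other.
#' @return Numeric vector of decline rates in pt/month (>= 0).
#' @export
#' @examples
#' delta_frs(36, 12)  # 1.0 pt/month
delta_frs <- function(alsfrs_r_at_baseline, disease_duration_at_baseline) {
  n <- max(length(alsfrs_r_at_baseline), length(disease_duration_at_baseline))
  score <- rep_len(alsfrs_r_at_baseline, n)
  dur <- rep_len(disease_duration_at_baseline, n)
  if (any(!is.na(dur) & dur <= 0)) {
    stop("disease duration must be positive", call. = FALSE)
  }
  if (any(!is.na(score) & (score < 0 | score > 48))) {
    stop("ALSFRS-R score must lie in [0, 48]", call. = FALSE)
  }
  (48 - score) / dur
}

#' Split trial follow-up into lead-in and interventional periods
#'
#' Visits up to `lead_in_months` form the observational lead-in; visits
#' from `lead_in_months` onwards form the interventional period. A visit
#' exactly at the boundary belongs to both: it closes the lead-in and is
#' the interventional period's first point. Interventional times are
#' re-centred so the period starts at 0.
#'
#' @param visits Tibble with at least `months_since_baseline`; further
#'   columns are carried through.
#' @param lead_in_months Length of the lead-in in months (default 3).
#' @return List with tibbles `lead_in` and `interventional` (the latter
#'   with `months_since_baseline` re-centred). Either may have zero rows.
#' @export
split_periods <- function(visits, lead_in_months = 3) {
  visits <- tibble::as_tibble(visits)
  stopifnot("months_since_baseline" %in% names(visits))
  t <- visits$months_since_baseline
  lead_in <- visits[!is.na(t) & t <= lead_in_months, ]
  interventional <- visits[!is.na(t) & t >= lead_in_months, ]
  interventional$months_since_baseline <-
    interventional$months_since_baseline - lead_in_months
  list(lead_in = lead_in, interventional = interventional)
}

#' Per-patient slopes across a whole cohort
#'
#' Applies [fit_patient_slope()] to every patient, optionally restricted to
#' the lead-in or interventional period (see [split_periods()]). Patients
#' with fewer than two distinct-time visits in the requested period are
#' excluded and listed in `attr(x, "excluded")`.
#'
#' @param x An `nfl_cohort`.
#' @param period `"full_followup"` (default), `"lead_in"` or
#'   `"interventional"`.
#' @param time_origin For the full follow-up, regress on months since
#'   `"baseline"` (default) or since `"onset"` (observational-cohort
#'   convention). The slope is identical either way; only the intercept
#'   moves. Ignored for split periods, which use their own origin.
#' @param lead_in_months Boundary for the period split (default 3).
#' @return Tibble with one row per evaluable patient (columns as in
#'   [fit_patient_slope()]) and attribute `"excluded"`: a tibble
#'   `patient_id`, `reason`.
#' @export
cohort_slopes <- function(x,
                          period = c("full_followup", "lead_in",
                                     "interventional"),
                          time_origin = c("baseline", "onset"),
                          lead_in_months = 3) {
  stopifnot(inherits(x, "nfl_cohort"))
  period <- match.arg(period)
  time_origin <- match.arg(time_origin)
  v <- x$visits
  if (period == "full_followup") {
    if (time_origin == "onset") {
      dur <- setNames(x$baselines$disease_duration_at_baseline,
                      x$baselines$patient_id)
      t <- ifelse(is.na(v$months_since_onset),
                  v$months_since_baseline + unname(dur[v$patient_id]),
                  v$months_since_onset)
      v$time <- t
      origin <- "onset"
    } else {
      v$time <- v$months_since_baseline
      origin <- "baseline"
    }
  } else {
    v <- split_periods(v, lead_in_months)[[period]]
    v$time <- v$months_since_baseline
    origin <- if (period == "interventional") "interventional_start" else "baseline"
  }
  pieces <- split(v, v$patient_id)
  ok <- vapply(pieces, function(d) {
    sum(!is.na(d$time)) >= 2 && dplyr::n_distinct(d$time[!is.na(d$time)]) >= 2
  }, logical(1))
  fits <- lapply(pieces[ok], function(d) {
    d <- d[!is.na(d$time), ]
    fit_patient_slope(d$time, d$alsfrs_r, patient_id = d$patient_id[1],
                      period = period, time_origin = origin)
  })
  out <- if (length(fits)) dplyr::bind_rows(fits) else
    fit_patient_slope(c(0, 1), c(0, 0))[0, ]
  excluded_ids <- setdiff(x$baselines$patient_id, out$patient_id)
  attr(out, "excluded") <- tibble::tibble(
    patient_id = excluded_ids,
    reason = paste0("fewer than 2 distinct-time visits in ", period, " period")
  )
  out
}
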