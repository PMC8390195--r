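#' Root-mean-square error of slope predictions
#'
#' `sqrt(mean((observed - predicted)^2))`, in pt/month.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 1).
#' @return Non-negative scalar.
#' @export
rmse <- function(observed, predicted) {
  .check_pair(observed, predicted, min_n = 1)
  sqrt(mean((observed - predicted)^2))
}

#' Coefficient of determination of predictions against observations
#'
#' `1 - sum((y - p)^2) / sum((y - m)^2)` with `m = mean(y)`. Ranges from
#' minus infinity to 1: 1 is perfect prediction, 0 matches predicting the
#' mean, negative values are worse than the mean.
#'
#' @inheritParams rmse
#' @return Scalar <= 1.
#' @export
coefd <- function(observed, predicted) {
  .check_pair(observed, predicted, min_n = 2)
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0) {
    stop("observed values are constant: coefficient of determination ",
         "undefined", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / denom
}

#' Relative change in residual variance
#'
#' `(var(y - p) - var(y)) / var(y)` with the sample (n - 1) variance:
#' -1 for perfect prediction, 0 for any constant (uninformative)
#' prediction, positive when predicting adds noise.
#'
#' @inheritParams rmse
#' @return Scalar >= -1.
#' @export
variance_change <- function(observed, predicted) {
  .check_pair(observed, predicted, min_n = 2)
  vy <- var(observed)
  if (vy == 0) {
    stop("observed values are constant: variance change undefined",
         call. = FALSE)
  }
  (var(observed - predicted) - vy) / vy
}

#' Fraction of predictions within a tolerance of the observation
#'
#' @inheritParams rmse
#' @param tol Tolerance in pt/month (default 0.5).
#' @return Fraction in `[0, 1]`.
#' @export
frac_within_tol <- function(observed, predicted, tol = 0.5) {
  .check_pair(observed, predicted, min_n = 1)
  mean(abs(observed - predicted) <= tol)
}

.check_pair <- function(observed, predicted, min_n) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) < min_n) {
    stop("need at least ", min_n, " observation(s)", call. = FALSE)
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop("missing values are not allowed here; drop them first",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-patient slope predictions under one of the three methods
#'
#' Builds the prediction each comparison method would issue at trial
#' baseline: the NfL model applied to baseline NfL and onset site,
#' the negated delta-FRS, or the OLS slope over the lead-in period.
#'
#' @param x An `nfl_cohort`.
#' @param method `"nfl_model"`, `"delta_frs"` or `"lead_in"`.
#' @param coefficients [nfl_coefficients()] used by the NfL method.
#' @param lead_in_months Lead-in length in months (default 3).
#' @return Tibble `patient_id`, `p` (predicted signed slope, pt/month);
#'   only patients for whom the method can produce a prediction appear.
#' @export
predicted_slopes <- function(x,
                             method = c("nfl_model", "delta_frs", "lead_in"),
                             coefficients = published_nfl_coefficients,
                             lead_in_months = 3) {
  stopifnot(inherits(x, "nfl_cohort"))
  method <- match.arg(method)
  b <- x$baselines
  switch(method,
    nfl_model = tibble::tibble(
      patient_id = b$patient_id,
      p = predict_slope(b$nfl_at_baseline, b$onset_site, coefficients)
    ),
    delta_frs = tibble::tibble(
      patient_id = b$patient_id,
      p = -delta_frs(b$alsfrs_r_at_baseline,
                     b$disease_duration_at_baseline)
    ),
    lead_in = {
      s <- cohort_slopes(x, period = "lead_in",
                         lead_in_months = lead_in_months)
      tibble::tibble(patient_id = s$patient_id, p = s$slope)
    }
  )
}

#' Score a prediction method against interventional-period slopes
#'
#' Pairs each patient's observed interventional-period slope (OLS over the
#' visits from the lead-in boundary onwards) with the prediction the chosen
#' method would have issued at trial baseline, and returns the four
#' validation metrics. Patients lacking the inputs a method needs (e.g. no
#' second interventional visit, or no lead-in slope) are dropped and
#' counted in `n_dropped`; each method therefore reports its own `n`.
#'
#' @inheritParams predicted_slopes
#' @param tol Tolerance for [frac_within_tol()] (default 0.5 pt/month).
#' @return Object of class `eval_metrics`: list with `method`, `rmse`,
#'   `coefd`, `variance_change`, `frac_within_tol`, `tol`, `n`,
#'   `n_dropped`, and `pairs` (tibble `patient_id`, `observed`,
#'   `predicted`).
#' @export
evaluate_method <- function(x,
                            method = c("nfl_model", "delta_frs", "lead_in"),
                            coefficients = published_nfl_coefficients,
                            lead_in_months = 3, tol = 0.5) {
  stopifnot(inherits(x, "nfl_cohort"))
  method <- match.arg(method)
  obs <- cohort_slopes(x, period = "interventional",
                       lead_in_months = lead_in_months)
  pred <- predicted_slopes(x, method, coefficients, lead_in_months)
  pairs <- dplyr::inner_join(
    tibble::tibble(patient_id = obs$patient_id, observed = obs$slope),
    tibble::tibble(patient_id = pred$patient_id, predicted = pred$p),
    by = "patient_id"
  )
  pairs <- pairs[stats::complete.cases(pairs), ]
  if (nrow(pairs) < 2) {
    stop("fewer than 2 evaluable patients for method '", method, "'",
         call. = FALSE)
  }
  structure(list(
    method = method,
    rmse = rmse(pairs$observed, pairs$predicted),
    coefd = coefd(pairs$observed, pairs$predicted),
    variance_change = variance_change(pairs$observed, pairs$predicted),
    frac_within_tol = frac_within_tol(pairs$observed, pairs$predicted, tol),
    tol = tol,
    n = nrow(pairs),
    n_dropped = nrow(x$baselines) - nrow(pairs),
    pairs = pairs
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat("<eval_metrics> method = ", x$method, "  (n = ", x$n,
      ", dropped ", x$n_dropped, ")\n", sep = "")
  cat(sprintf(
    "  RMSE %.3f pt/m | CoefD %.3f | variance change %+.3f | within %.1f pt/m: %.0f%%\n",
    x$rmse, x$coefd, x$variance_change, x$tol, 100 * x$frac_within_tol))
  invisible(x)
}
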