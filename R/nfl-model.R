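#' Coefficients of the NfL progression model
#'
#' The model predicts a patient's ALSFRS-R slope (pt/month, negative =
#' decline) from the natural log of the blood NfL concentration and the
#' site of disease onset:
#'
#' \deqn{slope = intercept + b_{lnNfL}\,\ln(NfL) + b_{spinal}\,S +
#'   b_{int}\,S\,\ln(NfL)}
#'
#' with \eqn{S = 1} for spinal and \eqn{S = 0} for bulbar onset.
#'
#' @param intercept Intercept in pt/month.
#' @param ln_nfl Coefficient of ln(NfL), pt/month per ln(pg/ml).
#' @param spinal Coefficient of the spinal-onset indicator, pt/month.
#' @param interaction Coefficient of the interaction
#'   \eqn{S \cdot \ln(NfL)}, pt/month per ln(pg/ml).
#' @return An object of class `nfl_coefficients`.
#' @seealso [published_nfl_coefficients], [predict_slope()]
#' @export
nfl_coefficients <- function(intercept, ln_nfl, spinal, interaction) {
  vals <- c(intercept = intercept, ln_nfl = ln_nfl, spinal = spinal,
            interaction = interaction)
  if (!all(is.finite(vals))) {
    stop("all four coefficients must be finite", call. = FALSE)
  }
  structure(as.list(vals), class = "nfl_coefficients")
}

#' Published coefficients of the NfL progression model
#'
#' The externally validated coefficient set
#' `slope = 4.45 - 1.13 ln(NfL) - 3.82 S + 0.83 S ln(NfL)`, developed on an
#' observational ALS cohort sampled at diagnosis. Shipped as the default
#' for [predict_slope()] and friends.
#'
#' @format An [nfl_coefficients()] object.
#' @export
published_nfl_coefficients <- nfl_coefficients(
  intercept = 4.45, ln_nfl = -1.13, spinal = -3.82, interaction = 0.83
)

#' @export
print.nfl_coefficients <- function(x, ...) {
  cat(sprintf(
    "ALSFRS-R slope = %.4g %+.4g ln(NfL) %+.4g S %+.4g S ln(NfL)   (S: 1 spinal, 0 bulbar)\n",
    x$intercept, x$ln_nfl, x$spinal, x$interaction))
  invisible(x)
}

# 1 for spinal, 0 for bulbar; accepts character/factor labels or 0/1.
.site_indicator <- function(onset_site) {
  if (is.numeric(onset_site)) {
    if (!all(onset_site %in% c(0, 1) | is.na(onset_site))) {
      stop("numeric onset_site must be 0 (bulbar) or 1 (spinal)",
           call. = FALSE)
    }
    return(as.numeric(onset_site))
  }
  s <- tolower(as.character(onset_site))
  if (any(!is.na(s) & !s %in% c("spinal", "bulbar"))) {
    stop("onset_site must be 'spinal' or 'bulbar'", call. = FALSE)
  }
  ifelse(s == "spinal", 1, 0)
}

#' Predict an ALSFRS-R slope from baseline NfL and onset site
#'
#' @param nfl_pg_ml Blood NfL concentration(s) in pg/ml (> 0).
#' @param onset_site `"spinal"` / `"bulbar"` (or 1 / 0); recycled against
#'   `nfl_pg_ml`.
#' @param coefficients An [nfl_coefficients()] object; defaults to
#'   [published_nfl_coefficients].
#' @return Predicted slope(s) in pt/month (negative = decline).
#' @export
#' @examples
#' predict_slope(100, "spinal")   # approximately -0.75
#' predict_slope(100, "bulbar")   # approximately -0.75 as well
predict_slope <- function(nfl_pg_ml, onset_site,
                          coefficients = published_nfl_coefficients) {
  stopifnot(inherits(coefficients, "nfl_coefficients"))
  n <- max(length(nfl_pg_ml), length(onset_site))
  nfl <- rep_len(as.numeric(nfl_pg_ml), n)
  if (any(!is.na(nfl) & nfl <= 0)) {
    stop("NfL concentration must be positive", call. = FALSE)
  }
  s <- rep_len(.site_indicator(onset_site), n)
  ln_nfl <- log(nfl)
  coefficients$intercept + coefficients$ln_nfl * ln_nfl +
    coefficients$spinal * s + coefficients$interaction * s * ln_nfl
}

#' ln(NfL) change needed to shift the predicted slope
#'
#' How many logarithmic units must ln(NfL) move to change the predicted
#' progression rate by `target_slope_change` pt/month, given the site of
#' onset. The answer is the absolute ratio of the target to the effective
#' ln(NfL) coefficient (main effect plus, for spinal onset, the
#' interaction).
#'
#' @inheritParams predict_slope
#' @param target_slope_change Desired slope change in pt/month.
#' @return Required ln(NfL) change in logarithmic units (>= 0).
#' @export
#' @examples
#' ln_nfl_sensitivity(0.5, "spinal")  # 1.67 log units
#' ln_nfl_sensitivity(0.5, "bulbar")  # 0.44 log units
ln_nfl_sensitivity <- function(target_slope_change, onset_site,
                               coefficients = published_nfl_coefficients) {
  stopifnot(inherits(coefficients, "nfl_coefficients"))
  n <- max(length(target_slope_change), length(onset_site))
  target <- rep_len(as.numeric(target_slope_change), n)
  s <- rep_len(.site_indicator(onset_site), n)
  eff <- coefficients$ln_nfl + s * coefficients$interaction
  if (any(eff == 0 & target != 0, na.rm = TRUE)) {
    stop("effective ln(NfL) coefficient is zero: sensitivity undefined",
         call. = FALSE)
  }
  ifelse(target == 0, 0, abs(target / eff))
}

#' NfL concentration where spinal and bulbar predictions coincide
#'
#' Solves the model for the unique NfL value at which the spinal and bulbar
#' branches predict the same slope: `exp(-spinal / interaction)`.
#'
#' @inheritParams predict_slope
#' @return The crossover concentration in pg/ml. If both the site and the
#'   interaction coefficients are zero the branches agree everywhere; `NA`
#'   is returned with a warning.
#' @export
#' @examples
#' crossover_nfl()  # about 100 pg/ml
crossover_nfl <- function(coefficients = published_nfl_coefficients) {
  stopifnot(inherits(coefficients, "nfl_coefficients"))
  if (coefficients$interaction == 0) {
    if (coefficients$spinal == 0) {
      warning("site and interaction coefficients are both zero: ",
              "spinal and bulbar predictions coincide everywhere")
      return(NA_real_)
    }
    stop("interaction coefficient is zero: the two branches are parallel ",
         "and never cross", call. = FALSE)
  }
  exp(-coefficients$spinal / coefficients$interaction)
}
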