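# Mixed-effects trial model. With the first interventional measurement
# a_i1 entering as a fixed unit-coefficient offset, the fit is run on
# (a_ij - a_i1); fixed effects are {1, t, t:treatment, p, p:t} and the only
# random effect is a per-patient slope on t (no random intercept).
.f_alt <- a_off ~ t + p + t:treatment + t:p + (0 + t | patient_id)
.f_null <- a_off ~ t + t:treatment + (0 + t | patient_id)

.normalize_per_patient <- function(x, what) {
  if (is.data.frame(x)) {
    cols <- names(x)
    val_col <- setdiff(cols, "patient_id")[1]
    if (!"patient_id" %in% cols || is.na(val_col)) {
      stop(what, " must be a named vector or a tibble with patient_id plus ",
           "a value column", call. = FALSE)
    }
    setNames(as.numeric(x[[val_col]]), as.character(x$patient_id))
  } else {
    if (is.null(names(x))) {
      stop(what, " must be named by patient_id", call. = FALSE)
    }
    setNames(as.numeric(x), names(x))
  }
}

# Interventional-period rows for patients with a prediction and >= 2
# distinct interventional time points; time re-centred per patient so t = 0
# at the first retained visit.
.base_design <- function(x, predictions, lead_in_months = 3) {
  stopifnot(inherits(x, "nfl_cohort"))
  p <- .normalize_per_patient(predictions, "predictions")
  v <- x$visits[x$visits$months_since_baseline >= lead_in_months, ]
  excluded <- list()
  has_p <- v$patient_id %in% names(p)[!is.na(p)]
  excluded$nopred <- tibble::tibble(
    patient_id = unique(v$patient_id[!has_p]), reason = "no prediction")
  v <- v[has_p, ]
  counts <- tapply(v$months_since_baseline, v$patient_id,
                   function(t) dplyr::n_distinct(t))
  enough <- names(counts)[counts >= 2]
  excluded$fewvisits <- tibble::tibble(
    patient_id = setdiff(names(counts), enough),
    reason = "fewer than 2 interventional time points")
  v <- v[v$patient_id %in% enough, ]
  d <- v |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$months_since_baseline, .by_group = TRUE) |>
    dplyr::mutate(t = .data$months_since_baseline -
                    min(.data$months_since_baseline),
                  a = .data$alsfrs_r,
                  a1 = .data$alsfrs_r[1]) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "t", "a", "a1")
  d$p <- unname(p[d$patient_id])
  attr(d, "excluded") <- dplyr::bind_rows(excluded)
  d
}

#' Build the design table for the mixed-effects trial model
#'
#' Retains only interventional-period visits (boundary visit included),
#' re-centres time to 0 at each patient's first retained visit, and joins
#' the per-patient slope prediction and treatment assignment. Patients
#' without a prediction, without an assignment, or with fewer than two
#' interventional time points are excluded and listed in
#' `attr(x, "excluded")`.
#'
#' @param x An `nfl_cohort`.
#' @param predictions Per-patient predicted slopes (pt/month): a named
#'   numeric vector or a tibble `patient_id`, `p`.
#' @param assignment Per-patient treatment indicator (0 control /
#'   1 treatment), same formats.
#' @param lead_in_months Start of the interventional period in months since
#'   trial baseline (default 3).
#' @return Tibble with columns `patient_id`, `t` (months since
#'   interventional start), `a` (ALSFRS-R), `a1` (ALSFRS-R at the
#'   patient's first interventional visit), `treatment`, `p`.
#' @export
build_design <- function(x, predictions, assignment, lead_in_months = 3) {
  d <- .base_design(x, predictions, lead_in_months)
  trt <- .normalize_per_patient(assignment, "assignment")
  if (!all(trt %in% c(0, 1))) {
    stop("assignment must be 0 (control) or 1 (treatment)", call. = FALSE)
  }
  has_t <- d$patient_id %in% names(trt)
  excl <- attr(d, "excluded")
  excl <- dplyr::bind_rows(excl, tibble::tibble(
    patient_id = unique(d$patient_id[!has_t]), reason = "no assignment"))
  d <- d[has_t, ]
  if (nrow(d) == 0) {
    stop("empty design: no evaluable patients", call. = FALSE)
  }
  d$treatment <- unname(trt[d$patient_id])
  arms <- unique(d$treatment)
  if (length(arms) < 2) {
    stop("single-arm design: all evaluable patients assigned to the same ",
         "group", call. = FALSE)
  }
  d <- d[, c("patient_id", "t", "a", "a1", "treatment", "p")]
  attr(d, "excluded") <- excl
  d
}

# REML fit with convergence bookkeeping. Singular (boundary) fits count as
# converged; optimizer failures and lme4 convergence warnings do not.
.safe_lmer <- function(formula, data) {
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(formula, data = data, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)),
      error = function(e) NULL
    ),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  if (is.null(fit)) converged <- FALSE
  if (converged && !is.null(fit@optinfo$conv$opt) &&
      fit@optinfo$conv$opt != 0) {
    converged <- FALSE
  }
  list(fit = fit, converged = converged)
}

.se_beta2 <- function(fit) {
  V <- as.matrix(stats::vcov(fit))
  sqrt(V["t:treatment", "t:treatment"])
}

.power_fit_record <- function(sf) {
  if (is.null(sf$fit)) {
    return(list(coefficients = NULL, se_beta2 = NA_real_,
                random_slope_sd = NA_real_, residual_sd = NA_real_,
                converged = FALSE, model = NULL))
  }
  vc <- lme4::VarCorr(sf$fit)
  list(
    coefficients = lme4::fixef(sf$fit),
    se_beta2 = .se_beta2(sf$fit),
    random_slope_sd = unname(attr(vc$patient_id, "stddev")["t"]),
    residual_sd = stats::sigma(sf$fit),
    converged = sf$converged,
    model = sf$fit
  )
}

#' Fit the alternative and null mixed-effects trial models
#'
#' The alternative model regresses the within-patient score change
#' `a - a1` on fixed effects intercept, time, time-by-treatment, the slope
#' prediction `p` and `p`-by-time, with one Gaussian random slope on time
#' per patient (no random intercept) and a Gaussian residual, estimated by
#' REML. The null model drops the two terms carrying predictive
#' information (`p` and `p:t`). Both report the standard error of the
#' treatment-effect coefficient (the `t:treatment` term), the quantity the
#' trial-size saving is built from.
#'
#' If the predictions are constant the predictor terms are dropped with a
#' warning and the alternative model equals the null model.
#'
#' @param design A design tibble from [build_design()].
#' @return Object of class `power_models`: list with elements `alt` and
#'   `null`, each holding `coefficients`, `se_beta2`, `random_slope_sd`,
#'   `residual_sd`, `converged` and the underlying `lmer` fit (`model`).
#' @export
fit_power_models <- function(design) {
  need <- c("patient_id", "t", "a", "a1", "treatment", "p")
  if (!all(need %in% names(design))) {
    stop("design must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  per_arm <- table(unique(design[, c("patient_id", "treatment")])$treatment)
  if (length(per_arm) < 2 || any(per_arm < 2)) {
    stop("need at least 2 patients per arm", call. = FALSE)
  }
  d <- as.data.frame(design)
  d$a_off <- d$a - d$a1
  null <- .power_fit_record(.safe_lmer(.f_null, d))
  if (isTRUE(var(d$p) == 0) || all(is.na(d$p))) {
    warning("predictions are constant: predictor terms dropped; ",
            "alternative model equals the null model")
    alt <- null
  } else {
    alt <- .power_fit_record(.safe_lmer(.f_alt, d))
  }
  structure(list(alt = alt, null = null), class = "power_models")
}

#' @export
print.power_models <- function(x, ...) {
  cat("<power_models>\n")
  cat(sprintf("  alt : SE(beta2) = %.4g  converged = %s\n",
              x$alt$se_beta2, x$alt$converged))
  cat(sprintf("  null: SE(beta2) = %.4g  converged = %s\n",
              x$null$se_beta2, x$null$converged))
  if (is.finite(x$alt$se_beta2) && is.finite(x$null$se_beta2)) {
    cat(sprintf("  trial-size saving: %.1f%%\n",
                saving_percent(x$alt$se_beta2, x$null$se_beta2)))
  }
  invisible(x)
}

#' Trial-size saving implied by a shrunken treatment-effect SE
#'
#' `100 * (1 - (se_alt / se_null)^2)`: the percent reduction in required
#' sample size when the analysis model includes predictive information.
#' Negative values mean the predictor *hurt* precision.
#'
#' @param se_alt,se_null Standard errors of the treatment-effect
#'   coefficient in the alternative and null models (> 0); recycled.
#' @return Saving(s) in percent.
#' @export
#' @examples
#' saving_percent(1, 1)          # 0
#' saving_percent(0.5, 1)        # 75
saving_percent <- function(se_alt, se_null) {
  n <- max(length(se_alt), length(se_null))
  a <- rep_len(as.numeric(se_alt), n)
  b <- rep_len(as.numeric(se_null), n)
  if (any(!is.finite(a) | !is.finite(b) | a <= 0 | b <= 0)) {
    stop("standard errors must be positive and finite", call. = FALSE)
  }
  100 * (1 - (a / b)^2)
}

#' Permutation Monte-Carlo distribution of trial-size savings
#'
#' Repeatedly assigns the cohort's evaluable patients to equal-sized
#' treatment and control groups at random (for odd n the arm sizes differ
#' by one, the larger side chosen by a fair coin), fits the alternative and
#' null mixed-effects models, and records the trial-size saving
#' ([saving_percent()]). Permutations in which either model fails to
#' converge are dropped and counted.
#'
#' @inheritParams build_design
#' @param n_perm Number of random assignments (default 10000).
#' @param seed Integer seed making the permutation stream reproducible;
#'   the global RNG state is restored afterwards.
#' @return Object of class `power_result`: list with `savings`
#'   (per-permutation percentages, converged only), `central_mean`,
#'   `central_median`, `ci_low`, `ci_high` (2.5/97.5 Monte-Carlo
#'   quantiles), `n_requested`, `n_converged`, `n_patients`, `seed`.
#' @export
permutation_power <- function(x, predictions, n_perm = 10000, seed = NULL,
                              lead_in_months = 3) {
  base <- .base_design(x, predictions, lead_in_months)
  ids <- unique(base$patient_id)
  n <- length(ids)
  if (n < 4) {
    stop("need at least 4 evaluable patients, have ", n, call. = FALSE)
  }
  d <- as.data.frame(base)
  d$a_off <- d$a - d$a1
  degenerate <- isTRUE(var(d$p) == 0)
  if (degenerate) {
    warning("predictions are constant: every permutation saves exactly 0%")
  }
  one <- function() {
    k <- n %/% 2L
    if (n %% 2L == 1L) k <- k + rbinom(1L, 1L, 0.5)
    treated <- sample(ids, k)
    d$treatment <- as.numeric(d$patient_id %in% treated)
    nl <- .safe_lmer(.f_null, d)
    if (!nl$converged) return(NA_real_)
    if (degenerate) return(0)
    al <- .safe_lmer(.f_alt, d)
    if (!al$converged) return(NA_real_)
    saving_percent(.se_beta2(al$fit), .se_beta2(nl$fit))
  }
  draw <- function() vapply(seq_len(n_perm), function(i) one(), numeric(1))
  savings <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  ok <- savings[!is.na(savings)]
  if (length(ok) == 0) {
    stop("no permutation produced two converged fits", call. = FALSE)
  }
  n_failed <- n_perm - length(ok)
  if (n_failed > 0) {
    warning(n_failed, " of ", n_perm,
            " permutation(s) dropped for non-convergence")
  }
  structure(list(
    savings = ok,
    central_mean = mean(ok),
    central_median = median(ok),
    ci_low = unname(quantile(ok, 0.025)),
    ci_high = unname(quantile(ok, 0.975)),
    n_requested = n_perm,
    n_converged = length(ok),
    n_patients = n,
    seed = seed
  ), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("<power_result>  ", x$n_converged, "/", x$n_requested,
      " permutations on ", x$n_patients, " patients\n", sep = "")
  cat(sprintf(
    "  trial-size saving: median %.1f%% (mean %.1f%%), 95%% MC CI [%.1f%%, %.1f%%]\n",
    x$central_median, x$central_mean, x$ci_low, x$ci_high))
  invisible(x)
}
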