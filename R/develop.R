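#' Per-patient candidate predictors for model development
#'
#' Extracts, from a cohort's baseline table, the candidate predictors of
#' the ALSFRS-R slope considered during model development: ln(NfL), the
#' spinal-onset indicator, sex, age at onset, BMI, disease duration,
#' delta-FRS (entered *signed*, i.e. as a slope prediction, so its
#' coefficient lives on the outcome's scale) and the baseline ALSFRS-R
#' score. Covariates absent from the cohort are `NA`.
#'
#' @param x An `nfl_cohort`.
#' @return Tibble with one row per patient: `patient_id`, `ln_nfl`,
#'   `onset_site` (1 spinal / 0 bulbar), `sex` (1 male / 0 female), `age`,
#'   `bmi`, `disease_duration`, `delta_frs` (signed, <= 0),
#'   `alsfrs_r_at_baseline`.
#' @seealso [develop_model()]
#' @export
candidate_predictors <- function(x) {
  stopifnot(inherits(x, "nfl_cohort"))
  b <- x$baselines
  tibble::tibble(
    patient_id = b$patient_id,
    ln_nfl = log(b$nfl_at_baseline),
    onset_site = .site_indicator(b$onset_site),
    sex = ifelse(is.na(b$sex), NA_real_, as.numeric(b$sex == "male")),
    age = b$age_at_onset,
    bmi = b$bmi,
    disease_duration = b$disease_duration_at_baseline,
    delta_frs = -delta_frs(b$alsfrs_r_at_baseline,
                           b$disease_duration_at_baseline),
    alsfrs_r_at_baseline = b$alsfrs_r_at_baseline
  )
}

.default_candidates <- c(
  "ln_nfl", "onset_site", "sex", "age", "bmi", "disease_duration",
  "delta_frs", "alsfrs_r_at_baseline", "ln_nfl:onset_site"
)

.interaction_parents <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

.is_interaction <- function(term) grepl(":", term, fixed = TRUE)

# Subsets of the candidate list that respect marginality: an interaction may
# only appear together with both of its parents.
.valid_subsets <- function(candidates) {
  subs <- unlist(
    lapply(seq_along(candidates), combn, x = candidates, simplify = FALSE),
    recursive = FALSE
  )
  keep <- vapply(subs, function(s) {
    ints <- s[vapply(s, .is_interaction, logical(1))]
    all(vapply(ints, function(i) all(.interaction_parents(i) %in% s),
               logical(1)))
  }, logical(1))
  subs[keep]
}

.term_pvalues <- function(fit) {
  sm <- summary(fit)$coefficients
  labs <- attr(stats::terms(fit), "term.labels")
  pv <- setNames(sm[labs, "Pr(>|t|)"], labs)
  # A perfect (zero-residual) fit yields NaN p-values; there is then no
  # statistical basis for removing anything, so such terms are kept.
  pv[!is.finite(pv)] <- 0
  pv
}

#' Develop a multivariable slope-prediction model
#'
#' Reproduces the two-pronged development procedure: (1) an all-subsets
#' comparison ranking every marginality-respecting combination of candidate
#' terms by adjusted R-squared, with an overall F-test of each subset
#' against the intercept-only model; (2) backward elimination, removing at
#' each step the non-significant term with the largest coefficient p-value
#' (two-sided t-test) until only significant terms remain. The intercept is
#' never removed, and model hierarchy is enforced: main effects that parent
#' a retained interaction are protected, and an interaction can only be in
#' a model alongside both parents.
#'
#' @param data Tibble with one row per patient containing the outcome
#'   column and every main-effect column named in `candidates` (see
#'   [candidate_predictors()]). Rows with missing values in any used column
#'   are dropped with a message; candidates that are entirely missing are
#'   dropped from the candidate list with a message.
#' @param outcome Name of the outcome column (a signed slope in pt/month).
#' @param candidates Character vector of candidate terms; interactions are
#'   written `"a:b"`. Defaults to the eight clinical/biomarker main effects
#'   plus the `ln_nfl:onset_site` interaction.
#' @param alpha Significance level for retaining a term (default 0.05).
#' @param all_subsets Compute the all-subsets ranking (default `TRUE`; set
#'   `FALSE` to skip it when only the eliminated fit is needed).
#'
#' @return An object of class `nfl_model_fit`: a list with `terms`
#'   (retained, without intercept), `estimates`, `std_errors`, `p_values`
#'   (each named, including `(Intercept)`), `adjusted_r2`, `r`
#'   (`sqrt(max(adjusted_r2, 0))`), `n`, `n_dropped`, `alpha`,
#'   `elimination` (tibble `step`, `term`, `p_value` in removal order),
#'   `subsets` (ranking tibble or `NULL`) and `model` (the final [lm()]
#'   fit).
#' @export
develop_model <- function(data, outcome = "slope",
                          candidates = .default_candidates,
                          alpha = 0.05, all_subsets = TRUE) {
  data <- tibble::as_tibble(data)
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  mains <- unique(unlist(lapply(candidates, .interaction_parents)))
  missing_cols <- setdiff(mains, names(data))
  if (length(missing_cols)) {
    stop("candidate column(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  all_na <- mains[vapply(mains, function(cn) all(is.na(data[[cn]])),
                         logical(1))]
  if (length(all_na)) {
    message("dropping candidate(s) with no observed values: ",
            paste(all_na, collapse = ", "))
    candidates <- candidates[
      !vapply(candidates,
              function(tm) any(.interaction_parents(tm) %in% all_na),
              logical(1))]
    mains <- setdiff(mains, all_na)
  }
  used <- c(outcome, mains)
  complete <- stats::complete.cases(data[used])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " patient(s) with missing candidate values")
  }
  d <- as.data.frame(data[complete, used])
  n <- nrow(d)
  if (n <= length(candidates) + 1) {
    stop("need more patients (", n, ") than candidate terms (",
         length(candidates), ") plus one", call. = FALSE)
  }

  fml <- function(terms) {
    if (length(terms) == 0) as.formula(paste(outcome, "~ 1")) else
      as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
  }
  full <- lm(fml(candidates), data = d)
  if (any(is.na(coef(full)))) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(coef(full))[is.na(coef(full))], collapse = ", "),
         call. = FALSE)
  }

  # Backward elimination with hierarchy protection.
  current <- candidates
  trace <- list()
  fit <- full
  repeat {
    if (length(current) == 0) {
      fit <- lm(fml(current), data = d)
      break
    }
    fit <- lm(fml(current), data = d)
    pv <- .term_pvalues(fit)
    ints <- current[vapply(current, .is_interaction, logical(1))]
    protected <- unique(unlist(lapply(ints, .interaction_parents)))
    removable <- setdiff(names(pv)[pv >= alpha], protected)
    if (length(removable) == 0) break
    worst <- removable[which.max(pv[removable])]
    trace[[length(trace) + 1]] <- tibble::tibble(term = worst,
                                                p_value = unname(pv[worst]))
    current <- setdiff(current, worst)
  }

  sm <- summary(fit)
  est <- sm$coefficients
  adj_r2 <- sm$adj.r.squared
  if (!is.finite(adj_r2)) adj_r2 <- 0

  subsets <- NULL
  if (all_subsets) {
    subs <- .valid_subsets(candidates)
    rows <- lapply(subs, function(s) {
      sfit <- summary(lm(fml(s), data = d))
      fs <- sfit$fstatistic
      tibble::tibble(
        terms = paste(s, collapse = " + "),
        n_terms = length(s),
        adjusted_r2 = sfit$adj.r.squared,
        f_statistic = unname(fs[1]),
        f_df1 = unname(fs[2]),
        f_df2 = unname(fs[3]),
        f_p_value = pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
      )
    })
    subsets <- dplyr::arrange(dplyr::bind_rows(rows),
                              dplyr::desc(.data$adjusted_r2), .data$n_terms)
  }

  elimination <- if (length(trace)) {
    dplyr::mutate(dplyr::bind_rows(trace), step = dplyr::row_number(),
                  .before = 1)
  } else {
    tibble::tibble(step = integer(), term = character(),
                   p_value = numeric())
  }

  structure(list(
    terms = current,
    estimates = est[, "Estimate"],
    std_errors = est[, "Std. Error"],
    p_values = est[, "Pr(>|t|)"],
    adjusted_r2 = adj_r2,
    r = sqrt(max(adj_r2, 0)),
    n = n,
    n_dropped = n_dropped,
    alpha = alpha,
    elimination = elimination,
    subsets = subsets,
    model = fit
  ), class = "nfl_model_fit")
}

#' @export
print.nfl_model_fit <- function(x, ...) {
  cat("<nfl_model_fit>  n = ", x$n,
      "  adjusted R^2 = ", signif(x$adjusted_r2, 3),
      "  (R = ", signif(x$r, 3), ")\n", sep = "")
  cat("retained terms: ",
      if (length(x$terms)) paste(x$terms, collapse = ", ") else
        "(intercept only)", "\n", sep = "")
  tab <- cbind(estimate = x$estimates, std_error = x$std_errors,
               p_value = x$p_values)
  print(signif(tab, 4))
  if (nrow(x$elimination)) {
    cat("eliminated (in order): ",
        paste(sprintf("%s (p = %.3g)", x$elimination$term,
                      x$elimination$p_value), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Extract NfL-model coefficients from a developed fit
#'
#' Converts a final [develop_model()] fit whose retained terms are exactly
#' `{ln_nfl, onset_site, ln_nfl:onset_site}` into an [nfl_coefficients()]
#' object usable with [predict_slope()].
#'
#' @param fit An `nfl_model_fit`.
#' @return An `nfl_coefficients` object.
#' @export
as_nfl_coefficients <- function(fit) {
  stopifnot(inherits(fit, "nfl_model_fit"))
  want <- c("ln_nfl", "onset_site", "ln_nfl:onset_site")
  if (!setequal(fit$terms, want)) {
    stop("fit does not have the NfL-model structure ",
         "{ln_nfl, onset_site, ln_nfl:onset_site}; retained terms: ",
         paste(fit$terms, collapse = ", "), call. = FALSE)
  }
  est <- fit$estimates
  nfl_coefficients(
    intercept = unname(est[["(Intercept)"]]),
    ln_nfl = unname(est[["ln_nfl"]]),
    spinal = unname(est[["onset_site"]]),
    interaction = unname(est[["ln_nfl:onset_site"]])
  )
}
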