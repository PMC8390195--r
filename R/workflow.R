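#' Run the full development--validation--power workflow
#'
#' Orchestrates the whole analysis: develop the multivariable slope model
#' on the development cohort; predict on each validation cohort with the
#' NfL model (frozen published coefficients by default, or the refit
#' coefficients with `refit = TRUE`), with delta-FRS and with the lead-in
#' slope; score all three methods against the observed
#' interventional-period slopes; and run the permutation power analysis
#' for each method and cohort. Per-patient observed-minus-predicted
#' differences are exported so that arm comparisons (mean or median
#' difference) can be made directly in an actual trial.
#'
#' All randomness is governed by `seed`, expanded deterministically into
#' one sub-seed per cohort-method permutation run.
#'
#' @param dev_cohort `nfl_cohort` used for model development.
#' @param validation_cohorts Named list of `nfl_cohort`s (may be empty).
#' @param coefficients Frozen coefficients used for validation predictions
#'   when `refit = FALSE` (default [published_nfl_coefficients]).
#' @param refit If `TRUE`, validation predictions use the coefficients
#'   refit on the development cohort (which must then retain the NfL-model
#'   structure, see [as_nfl_coefficients()]).
#' @param candidates Candidate terms for [develop_model()]; all-missing
#'   candidates are dropped automatically.
#' @param alpha Significance level for backward elimination.
#' @param all_subsets Whether the development step computes the
#'   all-subsets ranking.
#' @param n_perm Permutations per cohort and method.
#' @param seed Top-level integer seed.
#' @param lead_in_months Lead-in length in months.
#' @param tol Accuracy tolerance in pt/month for [frac_within_tol()].
#' @param dev_time_origin Time origin for development-cohort slopes
#'   (`"onset"`, the observational convention, or `"baseline"`).
#'
#' @return Object of class `workflow_report`: list with `development`
#'   (`nfl_model_fit`), `coefficients_used`, `validation` (per cohort:
#'   `metrics` and `power`, each per method, plus `differences`), `config`
#'   (echo of the tuning arguments), `seed` and `version`.
#' @export
run_workflow <- function(dev_cohort, validation_cohorts = list(),
                         coefficients = published_nfl_coefficients,
                         refit = FALSE,
                         candidates = .default_candidates,
                         alpha = 0.05, all_subsets = TRUE,
                         n_perm = 1000, seed = 1, lead_in_months = 3,
                         tol = 0.5, dev_time_origin = "onset") {
  stopifnot(inherits(dev_cohort, "nfl_cohort"))
  if (length(validation_cohorts) && is.null(names(validation_cohorts))) {
    names(validation_cohorts) <- paste0("V", seq_along(validation_cohorts))
  }

  dev_slopes <- cohort_slopes(dev_cohort, period = "full_followup",
                              time_origin = dev_time_origin)
  dev_data <- dplyr::inner_join(
    dev_slopes[, c("patient_id", "slope")],
    candidate_predictors(dev_cohort), by = "patient_id"
  )
  development <- tryCatch(
    develop_model(dev_data, outcome = "slope", candidates = candidates,
                  alpha = alpha, all_subsets = all_subsets),
    error = function(e) {
      stop("model development stage failed: ", conditionMessage(e),
           call. = FALSE)
    }
  )

  coefficients_used <- if (refit) as_nfl_coefficients(development) else
    coefficients

  methods <- c("nfl_model", "delta_frs", "lead_in")
  validation <- list()
  stage <- 0L
  for (nm in names(validation_cohorts)) {
    vc <- validation_cohorts[[nm]]
    stopifnot(inherits(vc, "nfl_cohort"))
    metrics <- list()
    power <- list()
    differences <- list()
    obs <- cohort_slopes(vc, period = "interventional",
                         lead_in_months = lead_in_months)
    for (m in methods) {
      stage <- stage + 1L
      metrics[[m]] <- tryCatch(
        evaluate_method(vc, m, coefficients_used, lead_in_months, tol),
        error = function(e) {
          stop("evaluation stage failed (cohort ", nm, ", method ", m,
               "): ", conditionMessage(e), call. = FALSE)
        }
      )
      preds <- predicted_slopes(vc, m, coefficients_used, lead_in_months)
      power[[m]] <- tryCatch(
        permutation_power(vc, preds, n_perm = n_perm,
                          seed = (seed + 997L * stage) %% .Machine$integer.max,
                          lead_in_months = lead_in_months),
        error = function(e) {
          stop("power stage failed (cohort ", nm, ", method ", m, "): ",
               conditionMessage(e), call. = FALSE)
        }
      )
      differences[[m]] <- metrics[[m]]$pairs |>
        dplyr::mutate(cohort = nm, method = m,
                      difference = .data$observed - .data$predicted,
                      .before = 1)
    }
    validation[[nm]] <- list(metrics = metrics, power = power,
                             differences = dplyr::bind_rows(differences),
                             n_interventional_slopes = nrow(obs))
  }

  structure(list(
    development = development,
    coefficients_used = coefficients_used,
    validation = validation,
    config = list(refit = refit, candidates = candidates, alpha = alpha,
                  n_perm = n_perm, lead_in_months = lead_in_months,
                  tol = tol, dev_time_origin = dev_time_origin),
    seed = seed,
    version = as.character(utils::packageVersion("nflprog"))
  ), class = "workflow_report")
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("<workflow_report>  nflprog ", x$version, ", seed ", x$seed, "\n",
      sep = "")
  cat("-- development --\n")
  print(x$development)
  cat("-- coefficients used for validation --\n")
  print(x$coefficients_used)
  for (nm in names(x$validation)) {
    cat("-- validation cohort ", nm, " --\n", sep = "")
    for (m in names(x$validation[[nm]]$metrics)) {
      print(x$validation[[nm]]$metrics[[m]])
      print(x$validation[[nm]]$power[[m]])
    }
  }
  invisible(x)
}
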