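Package: nflprog
Title: Neurofilament Light Based Prediction of ALS Progression and Trial Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models disease-progression rates in amyotrophic lateral
    sclerosis (ALS) from blood neurofilament light chain (NfL)
    concentrations measured at diagnosis. Provides per-patient ALSFRS-R
    slope estimation by ordinary least squares, development (all-subsets
    F-tests plus backward elimination) and application of a multivariable
    NfL prediction model with a site-of-onset interaction,
    external-validation metrics (RMSE, coefficient of determination,
    variance change), within-patient ln(NfL) stability summaries, a
    synthetic longitudinal cohort generator, and a mixed-effects
    permutation analysis that quantifies the trial-size saving a
    prognostic predictor buys in a placebo-controlled trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
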