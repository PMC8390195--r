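---
title: "Predicting ALS progression from blood NfL and quantifying trial power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ALS progression from blood NfL and quantifying trial power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nflprog)
```

## The problem

ALS trials track the ALSFRS-R, a 12-item functional questionnaire summing
to 0–48 points. A patient's progression rate is the slope of that score
over time, in points per month, estimated per patient by ordinary least
squares over their visits. Progression rates differ by an order of
magnitude between patients, so a treatment effect of realistic size is
buried in between-patient variance unless the analysis can anticipate each
patient's natural rate. `nflprog` implements and evaluates one such
anticipation: a linear model on blood neurofilament light chain (NfL)
measured once at diagnosis.

## The prediction model

With $S = 1$ for spinal and $S = 0$ for bulbar onset,

$$\widehat{\text{slope}} \;=\; \beta_0 + \beta_1 \ln(\text{NfL}) +
\beta_2 S + \beta_3 S \ln(\text{NfL}),$$

and the frozen, externally validated coefficient set shipped as
`published_nfl_coefficients` is $(4.45,\,-1.13,\,-3.82,\,0.83)$. NfL enters
on the natural-log scale (its raw distribution is heavily right-skewed).
The interaction makes the bulbar line steeper: one log unit of NfL moves
the bulbar prediction by 1.13 pt/month but the spinal prediction by only
$1.13 - 0.83 = 0.30$ pt/month. The two branches cross at
`crossover_nfl()` $\approx$ `r round(crossover_nfl(), 1)` pg/ml, where both
sites are predicted to lose about 0.75 pt/month.

`develop_model()` reproduces the development procedure on any cohort:

1. **All-subsets comparison.** Every marginality-respecting subset of the
   candidate terms (eight clinical/biomarker main effects plus the
   `ln_nfl:onset_site` interaction by default) is fitted by OLS and ranked
   by adjusted $R^2$, with the overall $F$-test against the intercept-only
   model reported per subset. Ties in adjusted $R^2$ favour fewer terms.
2. **Backward elimination.** Starting from the full model, the
   non-significant term (two-sided coefficient $t$-test,
   $\alpha = 0.05$) with the largest $p$-value is removed, one per step,
   until all remaining terms are significant. The intercept is never
   removed, and a main effect is protected while an interaction built on
   it remains in the model. No multiple-testing correction is applied —
   the selection is the classical stepwise procedure, reported together
   with its full elimination trace so the path is auditable.

Goodness of fit is summarised as adjusted $R^2$ and its square root $R$,
the scale on which internal validation of the published model was
reported ($R = 0.67$).

Two numerical edge cases are handled explicitly: a rank-deficient design
is refused with the collinear terms named, and a perfect (zero-residual)
fit — which yields undefined $t$ statistics — stops elimination rather
than removing terms on the basis of `NaN` $p$-values.

## Comparator predictions

Two strategies used by past trials serve as comparators:

- **ΔFRS**: $(48 - \text{baseline score}) / \text{months since onset}$,
  a decline *rate* stored positive by convention; it is negated whenever
  used as a prediction of a signed slope.
- **Lead-in**: the OLS slope over the first three months of trial
  follow-up. `split_periods()` assigns a visit exactly at the three-month
  boundary to *both* periods: it closes the lead-in and is the first
  interventional point. This mirrors how a real month-3 assessment is both
  the observation period's end and the interventional baseline, and it
  maximises the number of patients with two interventional time points.

Observational-cohort slopes regress on time since symptom onset, trial
slopes on trial time; the slope is invariant to that choice of origin
(only the intercept moves), so `cohort_slopes()` exposes it as an option
without it affecting any downstream result. No synthetic "48 points at
onset" anchor is ever added: only measured scores enter a slope fit. The
anchor convention exists in the literature, but it hard-codes the ΔFRS
assumption into the outcome; keeping the outcome purely observational
leaves ΔFRS as one *candidate* among others.

## Validation metrics

With observed interventional slopes $y$, predictions $p$ and
$m = \bar{y}$:

- $\mathrm{RMSE} = \sqrt{\mathrm{mean}((y-p)^2)}$ (the conventional
  root-mean-square error),
- $\mathrm{CoefD} = 1 - \sum (y-p)^2 / \sum (y-m)^2$, in
  $(-\infty, 1]$,
- variance change $= (\mathrm{var}(y-p) - \mathrm{var}(y)) /
  \mathrm{var}(y)$, in $[-1, \infty)$,

plus the fraction of predictions within 0.5 pt/month. Sample variances use
the $n-1$ denominator. Each method reports its own $n$: a patient without
a lead-in slope is dropped from the lead-in comparison only, never
silently aligned across methods.

## The power analysis

For a randomized placebo-controlled trial the analysis model is a linear
mixed-effects model on the interventional-period scores, time re-centred
to 0 at each patient's first interventional visit:

$$a_{ij} = a_{i1} + \beta_0 + (b_i + \beta_1)\,t_{ij} +
\beta_2\, t_{ij}\,\mathrm{treatment}_i + \beta_3\, p_i +
\beta_4\, p_i t_{ij} + \varepsilon_{ij},$$

where $a_{i1}$ is a fixed unit-coefficient offset (implemented by
modelling $a_{ij} - a_{i1}$, which is algebraically identical), $b_i$ is
the single per-patient Gaussian random slope (no random intercept), and
$p_i$ the slope prediction. Estimation is REML via `lme4`. The *null*
model drops $\beta_3$ and $\beta_4$. The trial-size saving is

$$100 \times \left(1 - (SE_{alt}/SE_{null})^2\right)$$

on the standard error of $\beta_2$ — the percent reduction in required
sample size at fixed power. `permutation_power()` repeats this over
`n_perm` random equal splits of the cohort into treatment and control
(odd $n$: arm sizes differ by one, the larger side chosen by a fair coin)
and reports the mean, the median and the 2.5%/97.5% Monte-Carlo quantiles
of the savings. Both central estimates are reported; the median is the
headline figure since it is robust to the occasional extreme assignment.
Permutations in which either model fails to converge are dropped and
counted (`n_converged`), with no jittered refits; singular fits — a random
slope variance estimated at the boundary — are legitimate REML solutions
and are kept. The whole stream is reproducible bit for bit from one
integer seed, and the global RNG state is restored afterwards.

A structural property of this statistic worth knowing: for a genuinely
uninformative predictor the savings distribution is centred slightly
*below* zero (typically a few percent for ~46 patients), because the two
predictor terms cost degrees of freedom and, by chance correlation with
the assignment, slightly inflate $SE_{alt}$. A prediction must carry real
information to overcome that fixed cost.

## NfL temporal stability

A baseline-only biomarker is only usable if it is stable on the trial
timescale. `stability_summary()` quantifies this per patient as the mean
relative deviation of $\ln(\text{NfL})$ from the patient's own mean
(in percent), aggregated per patient first and then averaged across
patients — the order matters and is fixed and documented. It also reports
the 2.5/97.5 empirical percentiles (linear interpolation between order
statistics, `quantile()` type 7) of the *signed* difference between the
baseline and first-follow-up $\ln(\text{NfL})$; the published interval for
the development cohort, $[-0.33, 0.79]$ log units, contains a negative
endpoint, so the quantity is the raw difference, not a magnitude.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes, so every module is testable offline. Defaults are the
development cohort's published characteristics:

| parameter | default | unit | provenance |
|---|---|---|---|
| `prop_spinal` | 0.78 | — | cohort composition |
| `ln_nfl_mean`, `ln_nfl_sd` | 4.63, 0.81 | ln(pg/ml) | baseline NfL distribution |
| `baseline_score_mean` | 42 | points | baseline ALSFRS-R |
| `duration_median_months` | 10.1 | months | median diagnostic delay |
| `visit_interval_months`, `followup_months` | 3, 18 | months | trial schedule |
| `true_coefficients` | published set | — | systematic slope component |
| `slope_noise_sd` | 0.45 | pt/month | calibrated, see below |
| `score_noise_sd` | 1.5 | points | visit-level measurement noise |
| `nfl_rel_fluct_sd` | 0.03 | fraction of ln level | within-patient NfL fluctuation |

The true slope is the model prediction plus
$\mathcal{N}(0, \texttt{slope\_noise\_sd})$ heterogeneity. No residual
slope dispersion was published; 0.45 pt/month is calibrated once so that
refitting the model on generated cohorts lands near the reported internal
validation $R \approx 0.67$, and is not revisited. Disease duration is
log-normal matched to the printed median (10.1 months) with
$\sigma_{\log} = 0.8$ chosen to resemble the printed interquartile range
(the IQR is not force-matched). Sex, age and BMI are not simulated — the
generator draws only what the slope model consumes — and `develop_model()`
simply drops all-missing candidates, so on synthetic data the effective
candidate list is {ln_nfl, onset_site, disease_duration, delta_frs,
alsfrs_r_at_baseline, ln_nfl:onset_site}.

Observed scores are the linear trajectory plus Gaussian noise, *rounded
and clipped to [0, 48]* — the integer floor/ceiling behaviour real scores
have and pure linear models ignore. Setting `score_noise_sd = 0` requests
idealized unrounded trajectories instead, so identifiability checks can
recover truth-table slopes exactly; with any positive noise the clipping
is active, and near-floor or improving patients' re-estimated slopes are
attenuated — a deliberate realism feature that tests must not confuse with
estimator bias. Longitudinal NfL at $t > 0$ fluctuates multiplicatively on
the log level, $\ln(\text{NfL})_t = \ln(\text{NfL})_0 (1 + e_t)$ with
$e_t \sim \mathcal{N}(0, 0.03)$; the $t = 0$ visit is the baseline draw
itself.

`generate_trial()` additionally randomizes 1:1 and shifts treated
patients' true slopes by `+treatment_effect` pt/month (a slowing), with
the pre-shift slope kept in the truth table.

**What passing synthetic tests do and do not show.** The generator's
world is linear, Gaussian, with a fixed visit grid, no dropout or
death-informed missingness, no covariate correlations (e.g. age–NfL), and
a within-patient NfL fluctuation that is symmetric — unlike the mildly
asymmetric follow-up differences seen in real cohorts. Tests passing under
it demonstrate that the estimators, the selection procedure and the power
machinery are *correct*, not that the model generalizes to any real
cohort; external validity rests on the deposited study data, which the
package can ingest via `read_cohort()` but does not redistribute.

## Reproducibility and problem sizes

Every stochastic routine takes an explicit seed and restores the global
RNG state (`withr::with_seed`). `run_workflow()` expands one top-level
seed deterministically into per-stage sub-seeds and echoes its full
configuration in the report, so a report is reproducible from itself. The
shipped test-suite simulations use cohorts of 16–400 patients, up to 100
seeded replicates for frequency properties, and permutation runs of
30–500 assignments; `n_perm = 10000` (the published setting) remains the
function default.

## Known limitations

- Linear trajectories only; sigmoidal or floor-adjusted models are out of
  scope by design.
- The per-patient OLS slope treats every visit equally; no within-patient
  autocorrelation beyond the power model's random slope.
- The published coefficients are used verbatim (4.45, −1.13, −3.82,
  0.83), though they appear to be printed rounded: the worked example
  (−0.75 pt/month at 100 pg/ml) reproduces only to two decimals, and the
  exact branch-crossing point is 99.7 pg/ml rather than a round 100.
- Survival endpoints, assay-level QC and eligibility screening are
  upstream of this package.
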