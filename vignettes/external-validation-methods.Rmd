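---
title: "Validating prediction models for bounded PRO scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating prediction models for bounded PRO scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promval)
```

## The problem

A prediction model for a patient-reported outcome (PRO) — here the five
EPIC-26 domain scores after surgery for localized prostate cancer — is only
useful outside its development cohort if it remains *calibrated*
(predictions neither systematically offset nor too extreme) and
*discriminating* (higher predictions go with higher observed scores) there.
`promval` implements the full external-validation procedure for such
models: cohort assembly from registry-style tables, multiple imputation of
missing covariates, a six-statistic validation battery per imputed
dataset, and pooling across imputations. Because real PRO registries are
rarely public, the package ships a first-class synthetic registry
generator with a known truth, so the whole pipeline is testable by
parameter recovery.

## The model under validation

Each domain model is linear in score units:

$$\hat y = \beta_0 + \beta_t \cdot t + \beta_b \cdot y_0 + \beta_a \cdot
\text{age} + \beta_p \cdot \text{PSA} + \sum_k \beta_k \cdot
\mathbb{1}[\text{level}_k]$$

with $t$ months post-treatment (a continuous term, or per-timepoint
indicators — both bases are supported because published longitudinal
models use either), baseline domain score $y_0$, and categorical terms for
Gleason grade, general health, race and treatment, each against a
reference level. Specs are plain YAML (`read_model_spec()`), written
canonically so load/save round-trips are byte-identical. Predictions are
**not** clipped to [0, 100] by default: the validation statistics should
see the model exactly as published, and whether a deployed tool clamps its
output is usually unknown; `clip_predictions` is available when it is
known to.

## Validation statistics and the median-regression choice

`compute_metric_set()` returns, per (domain, timepoint, imputation):

* $R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2$. For
  external validation no refitting happens, so $R^2 \le 1$ but unbounded
  below.
* MAE and RMSE with divisor $n$ (population forms).
* Calibration-in-the-large (CL): the intercept of a regression of $y$ with
  $\hat y$ as offset. Perfect value 0.
* Calibration slope (CS): the slope in a univariable regression of $y$ on
  $\hat y$. Perfect value 1; CS < 1 means predictions too extreme.
* c-index: over unordered pairs with distinct predictions, the fraction
  where $(\hat y_i - \hat y_j)(y_i - y_j) > 0$.

PRO domain scores pile up against 0 and 100 (in registry data the bowel,
hormonal and incontinence pre-surgery *medians* are 100). Least-squares
calibration estimates are dragged by that boundary mass, so CL and CS use
median (τ = 0.5 quantile) regression by default; `method = "mean"` gives
the least-squares variants, which the tests verify against closed-form
OLS.

### Ties in the c-index

The defining probability conditions on distinct predictions; observed
ties, under a strict reading of the inequality, count against concordance.
That strict reading is the default (`tie_policy = "as_printed"`). Since
discretely-scored domains produce many observed ties and some consumers
expect the Kendall-style convention, `"half_credit"` awards tied pairs
0.5. Both policies share the distinct-prediction denominator and both are
tested against an independent O(n²) enumeration oracle.

### The LAD solver

`lad_fit()` minimizes $\sum_i |y_i - \text{offset}_i - X_i\beta|$. Design:

* **Intercept-only fits** (the CL case) short-circuit to the *lower*
  median of the residuals. For even $n$ any value between the two central
  order statistics is a minimizer; the lower median is chosen because it
  coincides with a vertex of the equivalent linear program, keeping the
  shortcut consistent with the general solver.
* **General fits** run iteratively reweighted least squares with an
  annealed smoothing floor, then *vertex polishing*: an LAD optimum is
  always attained at a coefficient vector interpolating $p$ data points,
  so the solver enumerates $p$-subsets of the lowest-|residual| points and
  descends until no interpolating vertex improves the objective. This is
  exact at vertex solutions while staying fast at registry scale
  (n ≈ 2000 fits in milliseconds); a pure-R simplex would cost O(n²) per
  pivot there, which is why the LP lives in the test suite rather than the
  production path.
* LAD minimizers can be **non-unique** (flat optimal faces — a four-point
  example with one outlier has a whole interval of optimal slopes). The
  solver's contract is therefore on the achieved *objective*, and the
  tests compare objectives against an independent dense-simplex
  linear-programming oracle (200 random problems, relative tolerance
  1e-6), never coefficient vectors.

## Multiple imputation

Registry covariates — PSA and the general-health category above all — are
often missing for half the cohort, while the outcome scores themselves
must never be imputed (a subject without an observed score simply leaves
that domain's table). `impute_chained()` implements chained equations:

* continuous columns by predictive mean matching (PMM): a
  Bayesian-perturbed linear regression on the other predictors, type-1
  matching of drawn-coefficient predictions against least-squares
  predictions, and a uniform draw from the k = 5 closest observed donors.
  Imputed values are always members of the observed set — the property
  that keeps imputed PSA non-negative and realistically distributed;
* categorical columns by bootstrap polytomous regression
  (`nnet::multinom` on a resampled fit, category sampled from predicted
  probabilities);
* equal donor distances break toward the lowest row index before the
  uniform draw, making runs reproducible cell by cell;
* defaults of m = 100 datasets × 100 iterations mirror a full registry
  analysis; tests and the acceptance script run m = 20 × 10, which is
  where the imputation distribution has long stabilized for two or three
  incomplete columns.

The conditional models use the subject-level covariates and exclude
outcome and predicted scores by default (`predictors` is configurable):
with five domain outcomes per visit and two timepoints there is no single
natural outcome column to condition on, and the validation statistics
should not have the answer leaked into the covariates they are validated
with.

Validation statistics are computed on every imputed dataset and pooled by
`pool_metrics()` as mean, sample SD (divisor m − 1), median and quartiles.
Quartiles default to Tukey hinges (median-of-halves), with the
type-7 interpolation convention available — quantile conventions differ
across software and the choice is reported rather than hidden.

## The synthetic registry

`simulation_config()` defaults describe a prostatectomy PRO registry and
were fixed once from registry-typical summary tables:

* **age at diagnosis**: truncated normal, mean 65.4, SD 6.3, on [40, 80];
* **PSA**: log-normal (meanlog 1.88, sdlog 0.5) truncated below
  50 ng/mL, matching observed category fractions of roughly 14 / 66 / 18 /
  2 percent over < 4, 4–10, 10–20, ≥ 20. (Published tables sometimes print
  "ng/dL" for these magnitudes; conventional units are ng/mL and the
  package labels them so — the ≥ 50 exclusion threshold is unchanged
  either way.);
* **Gleason** 12 / 50 / 22 / 16 percent over ≤6, 3+4, 4+3, ≥8; **general
  health** 1 / 2 / 40 / 45 / 12 percent over Poor…Excellent;
* **baseline scores**: a two-part ceiling mixture — a point mass at 100
  plus a normal truncated to [0, 100) — per domain (e.g. incontinence:
  55 % at the ceiling, off-ceiling mean 85, SD 11). This is the simplest
  generator that reproduces both the means and the boundary pile-up
  (medians of 100) that motivates median-regression calibration;
* **outcomes**: the generating model's linear predictor plus Gaussian
  noise (residual SDs 22 / 20 / 10 / 9 / 9 score units across the five
  domains, of the order of reported validation RMSEs), then clipped to
  [0, 100]. Clipping is the minimal mechanism by which real scores attain
  their bounds; the clipped fraction is logged;
* **visits**: scheduled at 3, 12 and 24 months with 1.5-month timing
  jitter and 85 % response (92 % pre-surgery);
* **missingness**: logistic missing-at-random rules applied *after*
  outcome generation — PSA ~20 % and general health ~55 %, both increasing
  with age; age 2 %; per-domain outcome missingness between 2 % and 15 %.
  Rule probabilities are evaluated against the pre-masking tables, so the
  mechanism stays ignorable even when several rules interact, and a rule
  conditioning on an incompletely observed covariate is rejected outright
  (it would be MNAR).

What the generator deliberately does **not** emulate: treatment arms other
than surgery, informative dropout, item-level response processes (scores
are simulated at domain level; the EPIC-26 scorer has its own inverse
helper for tests), and within-subject correlation of visit-timing beyond
jitter. Passing parameter-recovery tests therefore demonstrates
correctness of the *pipeline*, not that any real registry satisfies MAR
or linearity.

## Cohort assembly conventions

* Window bounds are inclusive at both ends (a questionnaire at exactly 8
  or 16 months belongs to the 1-year cohort).
* Exact ties in distance-to-target resolve to the **earlier** visit —
  deterministic, and conservative in the sense of favoring less
  post-treatment recovery time.
* The baseline is the latest pre-surgery questionnaire, resolved *per
  domain*: a survey missing only its bowel items still provides the other
  baselines. This matches registries where per-domain missing counts
  differ within one instrument.
* A subject excluded by the clinical criteria is excluded with *all*
  triggered reasons logged; missing PSA never triggers the PSA criterion
  (it is imputed later). Every subject lands in exactly one of
  {included, no in-window visit, missing baseline, missing outcome} per
  domain and timepoint, and `assembly_flow()` checks that conservation.

## Numerical and degenerate-input choices

* Constant observed scores make $R^2$ undefined; constant predictions make
  CS and the c-index undefined. These raise a typed condition
  (`promval_undefined_metric`) naming the metric; pooling can carry them
  as flagged missing summaries instead.
* Calibration curves are local *linear* loess fits (tricube weights,
  default span 0.75, exact `surface = "direct"` evaluation) with
  pointwise 95 % bands — pointwise, not simultaneous, and the report
  footer says so.
* Pooled-metric CSVs print doubles with 17 significant digits so a written
  table reloads bit-exactly and identical runs produce byte-identical
  files.
* Every stochastic stage (generation, masking, each imputed dataset)
  derives from one user seed with fixed offsets, so the end-to-end
  pipeline is reproducible to the byte.

## Problem sizes used by the tests and acceptance script

Chosen as the package's own testing scale: parameter recovery and
miscalibration detection at n = 2000 subjects; the closed-form
concordance check at n = 20 000 with ten seeds; solver optimality on 200
random problems of n ≤ 50; the imputation-integrity check at n = 800 with
m = 20; the end-to-end acceptance run at the registry-typical n = 750 with
m = 20 × 10 iterations.

## Known limitations

* **Imputation noise attenuates accuracy metrics.** Imputing a covariate
  that carries model weight adds noise to predictions for the affected
  rows, which biases R², CS, MAE, RMSE and the c-index slightly toward
  the null relative to their complete-data values; CL, a median residual,
  is unaffected. The bias is first-order in the number of imputed rows
  while the between-imputation SD shrinks like its square root, so for
  hundreds of imputed rows the attenuation is *statistically visible*
  (several between-imputation SDs) even when it is substantively tiny
  (e.g. R² lower by ~0.01). This is expected behavior of multiple
  imputation in external validation, not an artifact of this
  implementation; comparisons of pooled metrics against complete-data
  values should expect it.
* Boundary clipping makes even the generating model slightly miscalibrated
  on heavily ceiling/floor-compressed domains (observed CS above 1 for a
  domain compressed at 0) — visible in the worked example and a faithful
  reflection of how bounded scores behave.
* The median-regression calibration slope is non-unique on degenerate
  configurations; only the objective is contractual.
* MAR only; no MNAR sensitivity analysis. No bootstrap confidence
  intervals — uncertainty is reported as across-imputation SD/IQR only.
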