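---
title: "Inferring hypoglycemia causes from self-care diaries: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring hypoglycemia causes from self-care diaries: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hypocause)
```

## The problem

People with type 1 diabetes experience hypoglycemia (blood glucose below
4 mmol/L by self-monitored fingerstick, SMBG) for reasons that are usually
behavioural: physical activity without dose adjustment, mistakes in
carbohydrate counting or meal timing, or mistakes in insulin dosage selection.
Clinicians reviewing a diabetes diary try to attribute each episode to one of
these broad cause families before suggesting changes to self-care. This
package implements that attribution problem as a reproducible statistical
pipeline over diary data: it represents each labelled episode as a fixed
vector of 83 numerical predictors, quantifies the association of each
predictor with each cause category using mixed-effects logistic regression,
and evaluates how well an automatic classifier can recover the cause labels
under subject-grouped cross-validation.

Real labelled diaries of this kind are clinical data and are not
redistributable, so the package ships a synthetic cohort generator
(`generate_cohort()`) that emulates the statistical structure the analyses
assume. Everything downstream — feature extraction, association analysis,
classification — operates identically on real diaries supplied in the
documented CSV interchange format (`read_diary_tables()`).

## The synthetic cohort

`cohort_config()` defaults describe the study setting the package targets:
54 subjects, a 180-day diary horizon, about 15 labelled episodes per subject
(drawn Poisson with log-normal inter-subject rate dispersion, SD 0.3 on the
log scale — the real inter-subject variance of episode rates is unknown, so it
is an explicit parameter), a 48/36/16% cause mix over
activity/food/medication (the observed 45/33/15% shares renormalised over the
three analysed classes), bolus-advisor context available for 40% of episodes,
and label confidence drawn with P(5) = 0.6, P(4) = 0.3, P(3) = 0.1 so that
roughly 90% of episodes survive the confidence ≥ 4 analysis filter.

Each subject gets latent self-care parameters (wake time ~ N(7:00, 45 min);
glucose set point 6–10 mmol/L with log-normal variability; carbohydrate ratio
8–12 g/U; basal dose 18–30 U; meal size ~50 g): 3–6 SMBG readings/day starting
shortly after wake, 2–4 meals/day with paired carbohydrate records and
quick-acting (QA) doses near grams/ratio, one basal dose/day, sporadic quiz
sessions. Timestamps are timezone-naive local times at minute resolution.

Injected episodes encode only the *directions* of cause-conditional effects;
the magnitudes are free parameters of `default_effect_profile()`, chosen once
to be clinically plausible and clearly present without being deterministic
class signatures:

* **Activity**: episode times concentrated in daytime (N(14:00, 2.5 h)); an
  exercise tag in the preceding advisor record with probability 0.85 when an
  advisor record exists; preceding QA dose shifted 1.5 U below the subject
  mean.
* **Food**: morning/evening-skewed times (bimodal at 8:30/19:30); preceding
  QA dose 2.5 U above the subject mean (a carbohydrate overestimate); a
  corrective carbohydrate intake soon after the episode (median 0.3 h).
* **Medication**: business-day-skewed (P = 0.85); the carbohydrate records in
  the 4 h before the episode removed with probability 0.7 (a longer
  fasting gap); the episode day's basal dose raised by 3 U.

Every category receives a corrective post-episode carbohydrate intake
(log-normal gap, median 1.2 h for non-food causes): patients treat any
hypoglycemia with carbohydrate, and a mechanism present in only one class
would otherwise act as a near-deterministic label leak — unrealistic and
numerically hostile to logistic estimation. `zero_effect_profile()` removes
all cause-conditional structure (uniform times, natural calendar, no dose
shifts, a common 0.8 h treatment gap) and is the basis of the null-calibration
tests.

What the generator does *not* emulate: glucose–insulin physiology (no meal
absorption or insulin action kinetics — episode glucose values are drawn, not
caused), diary omissions that correlate with behaviour (real patients
under-log food, especially hypo treatments), CGM traces, and free-text reason
idiosyncrasies. Tests passing on this cohort therefore demonstrate that the
*pipeline* is correct and unbiased (no leakage, calibrated nulls, sign
recovery), not that the classifier's absolute scores transfer to clinical
data.

## The 83-variable event representation

`represent_event()` maps an episode to the canonical registry
(`feature_registry()`) of 83 predictors: demographics (3), temporal context
(4), interpolated glucose curve (8), neighbouring readings (10), neighbouring
intakes (12), bolus-advisor context (6), 90-day statistics of glucose/QA
insulin/basal insulin/carbohydrate (10 + 8 + 8 + 8), and quiz engagement (6).
Choices worth spelling out:

* **Time of day.** The raw fraction-of-day `tod` wraps at midnight (23:55 and
  00:05 are 10 minutes apart but numerically distant), so the canonical
  vector instead carries the absolute hour offsets from noon (`cos_tod`) and
  midnight (`sin_tod`), both in [0, 12]. `tod` is still computed as an
  auxiliary column for single-variable statistics. Note that under these
  definitions `cos_tod + sin_tod = 12` identically; consequently only
  `sin_tod` enters the multiple regression (see below).
* **Glucose curve.** SMBG readings within ±3 h of the episode are
  interpolated with a monotonicity-preserving piecewise cubic Hermite
  polynomial (PCHIP), resampled every 5 minutes between the first and last
  reading, and summarised (mean, population SD, range, min, max,
  least-squares slope in mmol/L/h, sample skewness, excess kurtosis). The
  slope estimator and the 5-minute grid are package choices; shape statistics
  use biased (moment) estimators. Two readings degrade to linear
  interpolation, one to a constant.
* **Centering.** Neighbouring intake amounts are reported relative to the
  subject's own 3-month mean of that signal (computed strictly from data
  before the episode), so that "2 units" means two units more than usual *for
  this person*.
* **Thresholds.** Hyperglycemia > 10 mmol/L and in-target [4, 10] mmol/L are
  configurable (`window_config()`); the hypoglycemia threshold is the study's
  4 mmol/L definition.
* **Mean-crossing rate** is the number of sign changes of consecutive
  deviations from the window mean divided by the number of samples, giving a
  rate in [0, 1]. Slope means over the 90-day glucose series exclude
  consecutive-reading pairs more than 6 h apart (overnight gaps would
  otherwise dominate).
* **Missingness** is explicit `NA` end to end: the mixed models use
  complete cases per fit, and the classifiers impute training-fold means.
  `wake_up_offset` is the episode-day first reading (at/after 04:30) minus
  the 90-day median of such first readings, in hours, and is missing when the
  episode day has no earlier reading.

Three advisor settings (`ba_iob`, `ba_allowed_bgv`, `ba_carb_cu`) ride along
outside the canonical 83 because they are advisor *settings* rather than
episode-level advice; they participate in single-variable statistics only.

## Mixed-effects logistic association analysis

Because each subject contributes many episodes, per-feature association
strength is estimated with a random-intercept logit model: for episode *j* of
subject *i* and cause category *k*,

$$\operatorname{logit} p_{ijk} = \beta_0 + \beta_1 x_{ij} + b_i, \qquad
  b_i \sim N(0, \sigma_b^2),$$

fit by adaptive Gauss–Hermite quadrature (15 nodes; `fit_mixed_logit()`, lme4
backend) with Wald z statistics and the conventional star thresholds
(p < 0.05/0.01/0.001). Internally the design columns are scaled to unit SD
purely for numerical stability and the coefficients mapped back — an exact
reparametrisation. Features are centred, never scaled, before analysis, so
coefficients stay in per-unit log-odds.

The single-variable scan uses each feature's own complete cases (features
with different missingness use as much data as they have). The multiple
regression per category follows a fixed pipeline: drop advisor features and
the raw `tod` and `cos_tod`; drop features observed in fewer than 80% of
episodes (otherwise the shared complete-case set collapses around rarely
defined offsets); screen to the 40 best single-feature BICs; restrict to
shared complete cases; centre; iteratively remove columns with VIF ≥ 10
(exact-collinearity ties broken in favour of the better-BIC column); and fit
one multi-predictor model. Two guards handle degenerate situations loudly
rather than silently: unbounded Wald information (quasi-separation) triggers
a backoff that sheds the worst-BIC 20% of columns until the model is
estimable, and an adaptive-quadrature failure falls back to the Laplace
approximation with the event recorded in the fit's `messages`. No
multiple-testing correction is applied — the stars are raw per-test
significance levels, a presentational convention that should be read
accordingly.

`cos_tod` is excluded from the multiple regression a priori: it is the exact
affine complement of `sin_tod` (their sum is 12 h by construction), so only
one of the pair is estimable and `sin_tod` — hours from midnight, i.e.
"daytime-ness" — is the interpretable carrier of the time-of-day effect.

## Classification experiments

`run_cv_experiment()` reproduces the full protocol: subject-grouped outer
10-fold cross-validation (folds balance episode counts greedily; no subject
ever appears on both sides of any fold, outer or inner); within each outer
training sample, sequential floating forward selection (SFFS) over the
candidate features (advisor features excluded to maximise the usable sample),
scored by the mean F1 of an extremely randomized trees ensemble in a nested
subject-grouped 5-fold CV with inverse-frequency class weights
w_i = N_obs / (N_cl · N_obs,i); then a neural classifier trained on the
selected subset and evaluated once on the fold's validation subjects.

Design choices in this chain:

* **SFFS.** Forward additions must improve the inner-CV criterion by more
  than `min_improve = 0.002`: with strictly-positive improvement the CV noise
  floor lets pure-noise features accrete up to the cap. Floating removals
  require strict improvement. The subset is capped at 20 features by default
  and never empty. Subset scores are memoised; everything is deterministic
  given the seed.
* **Evaluator.** Extremely randomized trees (ranger, `extratrees` split rule,
  one random split per candidate), 50 trees on 63.2% subsamples with minimum
  node size 10. The evaluator only needs a stable ranking of candidate
  subsets; a small subsampled ensemble does that at a fraction of the cost of
  a large one, which matters because SFFS makes thousands of evaluator fits.
* **Neural classifier.** Three fully connected hidden layers whose width
  equals the selected subset size, ReLU, inverted dropout at 60%, a sigmoid
  (binary one-vs-rest) or 3-way softmax output, observation-weighted
  cross-entropy, full-batch Adam (learning rate 0.01), at most 300 epochs.
  The optimisation target (F1, recall or precision — class-averaged in the
  multiclass case, positive-class in the binary case) is not differentiable,
  so it is pursued by model selection rather than by the loss: 20% of the
  training fold is held out (class-stratified), the epoch checkpoint with the
  best held-out objective is kept (early stopping patience 30), and for
  binary models the decision threshold is then chosen on the same held-out
  split from a 0.05-step grid.
* **PCA variant.** In the `"pca"` feature space, training-fold features are
  imputed, standardised and rotated to principal components; SFFS then
  selects components. All imputation, standardisation and rotation parameters
  come from the training fold only and are applied unchanged to validation
  data.
* **Reporting.** Per-fold precision, recall, F1 and MCC per class (plus the
  multiclass MCC from the full confusion matrix), aggregated as mean ±
  population SD across folds — the same n-denominator convention the usual
  Python numerical stack prints. Zero-denominator conventions: undefined
  precision/recall/F1 are 0, MCC with a zero marginal is 0.

The outer 10-fold split is a single grouped partition; replications are
obtained by rerunning with different seeds.

## Numerical and degenerate-input conventions

Duplicate-time readings are averaged before interpolation; a window with no
readings yields all-missing curve features. Statistics requiring two samples
(SD, range, crossing rate, shape) are missing below that; zero-variance
windows make skewness/kurtosis missing rather than NaN. Outcome-constant
fits, single-class training folds, and fold plans with more folds than
subjects are errors, not warnings. Exact collinearity inside `vif_filter()`
is handled via infinite VIFs, dropped first. All RNG consumption is owned by
explicit seeds: a pipeline run writes its seeds to `manifest.json` and reruns
byte-identically.

## Problem sizes used by the shipped checks

The package's own test suite and the acceptance script run everything on
synthetic cohorts sized to exercise the full protocol while staying quick on
one CPU: parameter-recovery simulations use 200 subjects × 20 events × 100
replicates; SFFS recovery uses 800 episodes with 3 planted among 30 noise
features over 20 seeded runs with the subset cap at 5; the end-to-end
classification checks use cohorts of 20 subjects × 10 episodes with 5 outer
folds and a SFFS cap of 6–10; association sign-recovery uses 20 cohorts at
the full default study conditions (54 subjects, ~15 episodes each). The
mixed-model backend uses the BOBYQA optimiser, which on these designs
reaches the same optimum as the default optimiser measurably faster. These
sizes are stated here as the package's chosen study conditions for its own
verification; the exported defaults (54 subjects, 10 folds, cap 20) remain
the protocol defaults.

## Known limitations

* The association stars are unadjusted for multiplicity; with 83 predictors a
  5% false-star rate is expected under the null.
* The neural classifier is intentionally small and full-batch; it is a
  faithful implementation of the protocol, not a tuned production model.
* Synthetic-cohort results quantify pipeline correctness, not clinical
  performance; the generator's effect magnitudes are assumptions.
* One grouped 10-fold partition yields SDs that mix fold-size noise with
  subject heterogeneity; interpret the ± values as variability across
  validation groups, not confidence intervals.
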