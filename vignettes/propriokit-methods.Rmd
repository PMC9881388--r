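---
title: "Methods: normative scoring and classification of arm position matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative scoring and classification of arm position matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propriokit)
```

## The task and its parameters

In the arm position matching (APM) task a planar robot places the
participant's passive hand on one of four (2×2 grid, 20 cm spacing) or
nine (3×3 grid, 10 cm spacing) targets; the participant, without
vision, mirror-matches with the active hand. Each of six blocks visits
every target once in pseudo-random order, so a session yields 24 or 54
final positions. All analysis happens in the passive-hand frame after
reflecting the active hand about the body midline (x = 0); the matching
error of a trial is *mirrored active − target*, a convention carried
through every signed quantity.

Twelve parameters summarise a session:

* **Variability** (`var_x`, `var_y`, `var_xy`, cm): per-target sample
  standard deviation (n−1 denominator) of the matched position across
  the six blocks, averaged over targets; the combined value is the
  resultant `sqrt(var_x^2 + var_y^2)`. With six repeats the sample SD
  is biased low by the factor c4(6) ≈ 0.952; the package recovers a
  generator noise of σ as ≈ 0.952·σ, and the acceptance checks assert
  exactly that.
* **Contraction/expansion** (`ce_x`, `ce_y`, `ce_xy`, dimensionless):
  the x-range of the per-target mean matched positions (mean of the
  left column vs the right column; two or three targets per column by
  protocol) divided by the same range of the targets; analogously for
  rows in y. `ce_xy` is the shoelace area of the polygon through the
  mean matched positions of the border targets (all four, or the outer
  eight) divided by the target polygon area, with an absolute value so
  a crossed polygon cannot go negative.
* **Shift** (`shift_x`, `shift_y` signed cm, `shift_xy` ≥ 0): mean error
  per target, then averaged over targets.
* **Absolute error** (`ae_x`, `ae_y`, `ae_xy`, cm): mean of |error| over
  *all trials*, not per target first. The asymmetry with Shift's
  two-stage average is deliberate and preserved; with the balanced
  designs used here the two stages agree for the signed mean, but the
  absolute value does not commute with averaging.

## The normative model

Healthy-control values of each parameter are mapped to z-scores in
three steps, fitted per parameter on controls only
(`fit_normative()`):

1. **Box-Cox transform.** The power λ maximises the profile
   log-likelihood on the marginal control values (search interval
   [−3, 3]; ties within numerical tolerance resolve to λ = 1, the
   affine case). Signed parameters (`shift_x`, `shift_y`) are first
   shifted by `−min + 0.1·IQR` so the support is positive; other
   parameters get an offset only if the control sample itself touches
   zero. Fitting the transform on the marginal (before regression)
   follows the order in which the procedure is described; the residual
   distribution is then checked rather than re-transformed.
2. **Mean regression.** The transformed values are regressed on an
   intercept, age, age², sex, handedness (L and A contrasts against R)
   and platform (endpoint vs exoskeleton). Age is centred at 50 years
   purely to decorrelate the linear and quadratic terms — a
   reparameterisation, not a modelling change. The quadratic term is
   on by default (`quadratic_age = TRUE`) because aging effects on
   proprioception are not assumed linear over a 20–90 year span.
3. **SD regression.** The absolute residuals, scaled by
   `sqrt(pi/2)` (the half-normal mean correction, so the fitted value
   estimates the residual SD), are regressed on the same design.
   Predicted SDs are floored at 10% of the overall residual SD so a
   covariate extrapolation can never produce a non-positive scale.

`z = (boxcox(value + offset) − fitted mean) / fitted SD`. Values whose
shifted argument is non-positive (below the training support) are
clamped to half the smallest shifted training value with a warning;
they map to strongly negative z, which is the correct reading of "far
below every control". Skewness `mu3/sigma^3` and kurtosis `mu4/sigma^4`
of the fitted z-scores are stored per parameter with the
close-to-normal bands |skew| ≤ 0.8 and 2.4 ≤ kurtosis ≤ 3.6; failure
flags the parameter but does not disable it.

Design columns that are identically zero in a training sample (e.g. no
ambidextrous controls in a cross-validation fold) are dropped with a
warning rather than failing; a genuinely collinear design still raises
an error naming the offending terms. This keeps per-fold refits robust
without hiding real specification problems.

## The composite task score

Only one direction of deviation is abnormal for dispersion- and
magnitude-like parameters, so their z-scores are folded one-sided with
the zeta transform `zeta = sqrt(2)·erfcinv(erfc(±z/sqrt(2))/2)`
(equivalently, half the one-sided tail probability mapped back through
the normal quantile). The default sidedness map treats `var_*`, `ae_*`
and `shift_xy` as one-sided (high is bad) and `shift_x`, `shift_y`,
`ce_*` as two-sided: signed shifts and workspace ratios are abnormal in
either direction. The map is an argument everywhere, so a user who
prefers, say, one-sided contraction after a log transform can supply
that instead.

The RSS distance `sqrt(sum z_i^2 + sum zeta_j^2)` over the two-sided
and one-sided parameters is Box-Cox transformed, standardized by the
control mean and SD (no covariate regression at this stage), and
folded one-sided again. The resulting task score is non-negative,
zero only in the limit of best performance, and monotone in the RSS
distance. If the construction is exactly calibrated, a control exceeds
any threshold c with probability 2·(1 − Φ(c)): 5% at 1.96 and 1/1000
at 3.29. Controls above 3.29 are removed and the transform refitted,
iterating to a fixed point with a cap of five rounds (the cap has never
been reached in practice; one round almost always suffices).

Numerical guards: tail probabilities inside the zeta transform are
clipped to [1e-300, 1 − 1e-16], so the transform stays finite for any
finite z; RSS values at or below the transform support are clamped
like parameter values, with a warning.

## The cut-off technique

A session is impaired on a one-sided parameter when its zeta exceeds
1.96, on a two-sided parameter when |z| does, and overall when the task
score does — strictly greater, so a score of exactly 1.96 is
unimpaired. Cross-validated rates (`impairment_rates_cv()`) refit both
the normative and the task-score model on each training fold's controls
and classify the held-out stroke sessions; refitting is what gives the
fold-to-fold SD meaning and avoids leaking test controls into the
normative fit. Folds are stratified by group. `K = 1` degenerates to
whole-sample fitting, which the tests use as a consistency check.

## The classifier comparison

Six models classify sessions as stroke vs control from the 12 z-scored
parameters under stratified K-fold cross-validation (default K = 10).
Min-max scaling is fitted on each training fold only and applied
affinely to the test fold (no clipping); a checksum of the raw test
rows before and after each fold asserts the test data are untouched.

Fixed configurations:

| model | settings |
|-------|----------|
| LR  | L2-penalised logistic regression (penalty 1.0), Newton/IRLS, tolerance 1e-4, ≤ 100 iterations |
| DT  | Gini impurity, best-split, max depth 4, min leaf 1, min split 2 |
| RF  | 100 trees, Gini, min split 2, min leaf 1 |
| RFT | randomized search (50 seeded candidates, 3-fold inner CV, accuracy objective) over number of trees, max depth, features per split, min node size to split, min leaf size |
| SVM | RBF kernel, cost 1, tolerance 1e-3, 200 MB kernel cache, probability estimates enabled |
| DNN | 12-8-1 MLP (ReLU, ReLU, sigmoid; 269 trainable weights), binary cross-entropy, RMSprop (lr 0.001, rho 0.9), batch 10, 100 epochs |

The LR and the MLP are implemented in the package so the stopping
rules, penalty and optimiser match the stated recipe exactly and every
random element (weight initialisation, batch shuffling, candidate
sampling, permutations) flows from a single seed. The tuned forest's
candidate list always contains the default forest, so its inner-CV
score cannot fall below the untuned configuration; ties resolve to the
earliest (default) candidate.

ROC scores are class probabilities, except the SVM which uses its
decision value (oriented so larger means stroke). Per-fold ROC curves
are linearly interpolated onto a common 101-point FPR grid, averaged
pointwise, and integrated by the trapezoid rule. Feature importance is
mean impurity decrease for the tree models and seeded permutation
importance (mean log-loss increase over 20 permutations per feature,
floored at zero) for LR and SVM — the closest well-defined reading of
"perturbation of a given feature"; all importances are normalised to
sum to 100. The MLP exposes no importance and asks for one raises an
error.

## The synthetic cohort generator

No patient-level APM dataset is publicly deposited, so the generator
(`generate_cohort()`) produces cohorts with the statistical structure
the analysis assumes. A session's behaviour is an affine distortion of
the ideal mirror — per-axis gain about the active workspace centroid,
constant offset — plus independent per-trial Gaussian noise; the robot
places the passive hand exactly. This is the minimal model producing
the three canonical impairment phenotypes: inflated variability,
workspace contraction/expansion, and spatial shift.

Defaults (all configurable per axis):

* **Cohort structure:** 465 control and 429 stroke sessions; controls
  tested once per arm as paired sessions sharing covariates but with
  independent traits; control ages 20–88 (mean 51), stroke 18–92
  (mean 63); handedness ≈ 93/6/1% R/L/A; a 70/30 exoskeleton/endpoint
  platform mix and 60/40 nine-/four-target protocol mix so the
  normative covariates all vary.
* **Control traits:** trial noise SD lognormal around 0.9 cm (x) /
  1.1 cm (y) with 0.25 log-SD between participants, +0.8%/year age
  slope and small male/left-handed/endpoint multipliers (1.05, 1.03,
  1.08); gains lognormal around 1 (log-SD 0.08) with a slight
  age-related contraction; shifts Gaussian, mean 0.5 cm, SD 1.2 cm.
  The covariate effects exist so the normative regressions have signal
  to recover; their magnitudes are package choices, not estimates.
* **Stroke group:** an impaired fraction (default 0.44) whose noise is
  multiplied by lognormal(log 2.2, 0.4), gains by lognormal(−0.08,
  0.12) (median contraction), and shifts widened by an extra 1.5 cm
  SD; the unimpaired remainder get a mild 1.15 noise multiplier,
  reflecting sub-threshold deficits. These values were fixed once to
  reproduce the qualitative impairment profile — variability
  parameters flagging roughly half the stroke group at the 95%
  cut-off, shifts the fewest, the overall rate near the impaired
  fraction — and are deliberately not tuned further.

What the generator does **not** emulate: movement kinematics (speed
profiles, timing), hemispatial neglect or other lateralised error
structure, non-Gaussian trial noise, correlations between gain and
noise deficits, and session-to-session learning. Passing tests
therefore demonstrate the correctness and calibration of the scoring
machinery under its own assumptions, not the clinical performance of
the cut-off or the classifiers on real patients.

## Problem sizes and verification

The test suite verifies, among others: exact agreement (1e-9) of the
parameter formulas with an independent naive reimplementation on 100
random sessions; null calibration of the task score on 10^5
standard-normal z-draws (5% above 1.96, ~1/1000 above 3.29);
z-score calibration on 10,000 held-out controls from a 5,000-control
normative fit (per-parameter mean within ±0.05, SD within 0.95–1.05,
KS distance < 0.03, all diagnostics passing); recovery of a unit
generator noise as c4(6) ≈ 0.952 over 10,000 sessions; a ~5 ± 1%
per-parameter false-flag floor on the held-out controls; chance-level
(0.5 ± 0.03) accuracy of all six classifiers under shuffled labels on
a 2,000-session cohort and > 0.95 under full separation; AUC
monotonicity in the injected effect size; and dominance of the
y-variability features when only y-noise is inflated. These sizes were
chosen so Monte-Carlo error is small against each tolerance while the
suite stays comfortably runnable on a single CPU.

## Known limitations

* The sidedness of the contraction/expansion ratios is a documented
  choice (two-sided); a production implementation might fold them
  one-sided after a reciprocal or log transform.
* The Box-Cox transform is fitted marginally, so when covariate effects
  are strong the conditional residuals can retain mild skew; the
  diagnostics expose this per parameter.
* The SD regression is linear in the covariates; strongly
  multiplicative heteroscedasticity is only approximated (the floor
  guards the tails).
* Cross-validated impairment-rate SDs mix fold-assignment and refit
  variability; they are descriptive, not standard errors.
* With 4-target protocols the contraction/expansion columns/rows
  contain two targets instead of three and `ce_xy` uses the full
  quadrilateral; the two protocols are therefore not exactly
  comparable parameter-by-parameter, which mirrors how the task is
  administered.
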