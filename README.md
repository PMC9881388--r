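# propriokit

Analysis of robotic **Arm Position Matching (APM)** assessments of
proprioception, aimed at researchers working with planar rehabilitation
robots (exoskeleton or endpoint) who need to turn trial-level matching
data into standardized impairment calls and classifier benchmarks.

In the APM task a robot moves one (passive) arm to a target on a 2×2
(20 cm) or 3×3 (10 cm) grid and the participant mirror-matches with the
other (active) arm, without vision. From six blocks of trials the
package computes twelve kinematic parameters — trial-to-trial
variability, spatial contraction/expansion ratio, systematic spatial
shift, and absolute error, each in x, y, and combined:

    Var_xy   = sqrt(Var_x^2 + Var_y^2)
    CE_x     = range_x(active) / range_x(passive)        (CE_xy: area ratio)
    Shift_xy = sqrt(Shift_x^2 + Shift_y^2)
    AE_xy    = sqrt(AE_x^2 + AE_y^2)

Each parameter is standardized against a **normative model** fitted on
healthy controls: a Box-Cox power transform toward normality, a linear
regression of the transformed mean on age, sex, handedness and robotic
platform, and a second regression modelling the residual standard
deviation on the same covariates; `z = (boxcox(value) − mean) / sd`.
Skewness and kurtosis of the resulting scores are checked against the
close-to-normal bands `|sqrt(b1)| ≤ 0.8` and `2.4 ≤ b2 ≤ 3.6`.

One-sided parameters (where only large values are bad) are folded into
**zeta scores**, `zeta = sqrt(2)·erfcinv(erfc(±z/sqrt(2))/2)`, and the
Euclidean norm over all z/zeta scores (the RSS distance) is Box-Cox
standardized on controls and folded once more into a non-negative
**task score**: 0 is best performance, a score above 1.96 marks
impairment at the 95% control cut-off, and controls above 3.29
(1 in 1000) are removed as outliers during fitting. The same cut-off
rule applies per parameter (`|z|` or zeta against 1.96).

On top of the cut-off technique the package benchmarks six classifiers
(logistic regression, decision tree, random forest, tuned random
forest, RBF SVM, and a 12-8-1 MLP) under stratified 10-fold
cross-validation with leak-free min-max scaling, reporting per-fold
accuracy/precision/recall/F1, mean ROC curves with AUC, and feature
importances. A seeded synthetic cohort generator stands in for patient
data, emulating mirror-matching with per-participant trial noise,
workspace gain, and spatial shift, with covariate-dependent control
traits and a heterogeneous stroke group.

## Worked example

```r
library(propriokit)

co     <- generate_cohort(cohort_config(n_control = 300, n_stroke = 200), seed = 1)
params <- compute_parameters(co$trials, co$participants)
round(params[1, -1], 3)
#>   var_x var_y var_xy ce_x  ce_y ce_xy shift_x shift_y shift_xy  ae_x  ae_y ae_xy
#> 1 0.468 1.418  1.493 1.23 1.073 1.321   0.806    0.35    0.878 1.769 1.239 2.159

is_ctrl <- co$participants$group == "control"
norm    <- fit_normative(params[is_ctrl, ], co$participants[is_ctrl, ])
norm
#> Normative APM model: 12 parameters fitted on 300 control sessions
#> Design terms: (Intercept), age, age2, sexM, handL, handA, platform_endpoint

z   <- predict(norm, params, co$participants)
tsm <- fit_task_score(z[is_ctrl, ])
tsm
#> APM task-score model: 300 retained controls, lambda = 0.368
#> 0 control outlier(s) removed in 1 iteration(s) at threshold 3.29

sc  <- task_score(z, tsm)
imp <- classify_impairment(z, sc)
mean(imp$overall[!is_ctrl])   # stroke sessions impaired overall: 0.46
mean(imp$overall[is_ctrl])    # control false-flag rate: 0.053

cv <- impairment_rates_cv(params, co$participants, K = 10, seed = 1)
head(cv$rates[order(-cv$rates$mean_rate), ], 4)
#>    parameter mean_rate sd_rate
#> 3     var_xy      0.51    0.08
#> 13   overall      0.46    0.12
#> 1      var_x      0.43    0.12
#> 2      var_y      0.39    0.10
```

The first row of parameters reads: this control session matched targets
with ~0.5 cm (x) / 1.4 cm (y) trial-to-trial variability, slightly
expanded their perceived workspace (ratios above 1), and showed a small
rightward/forward constant shift under a ~2.2 cm mean absolute error.
At the 95% cut-off, 5.3% of controls are flagged (the nominal floor)
against 46% of the simulated stroke group, and variability parameters
flag far more stroke sessions than shifts — the expected impairment
profile. `run_experiment(z[, apm_parameter_names()], co$participants$group)`
adds the six-model comparison; `run_pipeline()` chains everything and
writes CSV/JSON reports, and `inst/scripts/propriokit` exposes the same
flow from a shell.

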