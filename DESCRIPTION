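Package: propriokit
Title: Robotic Arm Position Matching Analysis for Proprioceptive Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for robotic Arm Position Matching (APM)
    assessments of proprioception after stroke. Computes the twelve APM
    kinematic parameters (trial-to-trial variability,
    contraction/expansion ratio, systematic spatial shift, absolute
    error; each in x, y and xy), standardizes them against a
    covariate-adjusted normative model of healthy-control performance
    (Box-Cox transform followed by dual mean/standard-deviation
    regressions on age, sex, handedness and robotic platform), builds a
    composite one-sided task score from the root-sum-square of
    standardized scores, classifies impairment by the 95% control
    cut-off, and compares that rule with cross-validated machine
    learning classifiers (logistic regression, decision tree, random
    forest with and without hyperparameter tuning, support vector
    machine, and a small neural network). Includes a seeded synthetic
    cohort generator emulating the 4-target and 9-target matching
    protocols for development and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    rpart,
    randomForest,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
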