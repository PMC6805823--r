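Package: phonocad
Title: Acoustic Risk Scoring and Reclassification for Stable Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and evaluation pipeline for heart-sound based rule-out
    testing of stable coronary artery disease. Generates synthetic patient
    cohorts with phonocardiogram recordings, segments heart sounds into
    systolic and diastolic periods, extracts an eight-feature acoustic
    profile, combines it through a shrinkage linear discriminant and a
    logistic fusion with age, sex and hypertension into a 0-99 risk score,
    applies a pre-test-probability based reclassification scheme with the
    binary net reclassification index, and provides the full diagnostic
    evaluation toolkit (exact binomial confidence intervals, likelihood
    ratios, Bayesian post-test probabilities, ROC/AUC with DeLong and
    Hanley comparisons, repeated stratified cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    pROC,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
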