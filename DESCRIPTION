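Package: gaitwin
Title: Digital-Twin Gait Analysis and Risk Stratification for Preterm Toddlers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a preterm/full-term toddler cohort with wearable
    inertial-sensor gait recordings, detects gait events from shank angular
    velocity, computes a battery of temporal, symmetry, variability,
    harmonic-ratio, multiscale sample-entropy and recurrence-quantification
    metrics on trunk acceleration, stores each child's clinical and motor
    data in an FHIR-flavoured digital-twin document with RDF/knowledge-graph
    export, and runs risk-stratification analyses (repeated k-means with
    feature importance and kernel density summaries, class-imbalance
    handling via class weights and SMOTE, cross-validated classifier search,
    permutation feature attribution).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    signal,
    withr,
    Rcpp,
    glmnet,
    e1071,
    rpart,
    randomForest,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
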