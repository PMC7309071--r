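Package: aclgait
Title: Wearable-IMU Gait Analysis and Classification of Post-ACL Athletes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of lower-limb inertial sensor recordings from
    a run-and-sidestep task: synthetic multi-sensor IMU data generation for
    healthy and post-ACL cohorts, temporal alignment and shank-frame rotation,
    shank-gyroscope gait event detection with the six temporal gait parameters
    (gait cycle time, stance and swing phase, their relative versions, and
    cadence), a named registry of time- and frequency-domain features including
    movement-smoothness measures (dimensionless jerk, sample entropy, spectral
    arc length), the group-level statistical analysis (Levene's test, two-way
    ANOVA, Cohen's d, exact noncentral-t power analysis), and a
    subject-stratified leave-one-subject-out machine-learning evaluation
    protocol with confusion-matrix-derived metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    class,
    e1071,
    jsonlite,
    nnet,
    signal,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
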