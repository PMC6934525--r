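Package: dualgait
Title: Dual-Task Gait and Calculation Analysis for Cognitive Score Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates Kinect-style dual-task sessions (stepping in place
    while answering two-alternative arithmetic questions), extracts the
    twelve single- and dual-task gait and calculation features (step-interval
    statistics, knee-raise amplitude statistics, answer accuracy and speed),
    estimates Mini-Mental State Examination (MMSE) scores by regression
    (Bayesian-regularized neural network, random forest, linear support
    vector regression) under leave-one-subject-out cross-validation,
    classifies subjects below the MMSE-24 screening threshold, and provides
    feature-importance, leave-feature-out ablation, feature-set comparison,
    trial-experience and learning-curve analyses with Bonferroni-corrected
    contrasts. Session streams are stored as JSON-Lines, feature tables and
    reports as CSV, and run configurations as YAML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
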