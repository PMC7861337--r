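Package: fetalga
Title: Gestational-Age Estimation and Growth-Restriction Screening from
    Doppler-Derived Fetal Heart Rate and Maternal Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating gestational age from one-dimensional
    Doppler ultrasound recordings and maternal blood-pressure readings, and
    for screening possible intrauterine growth restriction from the
    estimation error. Implements autocorrelation-based fetal heart rate
    extraction from the Doppler envelope, cardiotocographic cleaning,
    baseline estimation, Dawes acceleration/deceleration detection and
    phase-rectified signal averaging, a 37-feature panel of linear,
    non-linear, spectral and maternal hemodynamic indexes, ADASYN class
    balancing, mRMR and gradient-boosting feature ranking, grouped repeated
    cross-validation of Elastic Net, support-vector and boosted-tree
    regressors, and a screening statistic based on the difference between
    menstrual-dating and estimated gestational age. A synthetic cohort
    generator with known ground truth supports offline testing of every
    stage.
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
    glmnet,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
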