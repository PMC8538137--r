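Package: imufall
Title: Multi-IMU Fall Detection for Body-Worn Sensor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for detecting falls from a body-worn network of
    nine inertial measurement units (IMUs) sampled at 15 Hz. Includes a
    kinematic simulator of falls and fall-like activities for generating
    labeled multi-node recordings, TRIAD-style global calibration of every
    node into a shared north-east-up frame from gravity and magnetic
    reference vectors, Mahony attitude estimation (quaternions and Euler
    angles), sliding-window statistical feature extraction (mean, range,
    standard deviation, mean absolute deviation over 13 channels per node),
    a stacked-LSTM fall/non-fall classifier trained with Adam, and an
    evaluation suite with sensitivity/specificity/accuracy, ROC/AUC,
    per-activity breakdowns and a sensor-placement ablation over the 30
    standard placement combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
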