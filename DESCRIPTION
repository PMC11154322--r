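Package: imuposture
Title: Low-Cost IMU Motion Capture and Operation-Posture Recognition
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for six-sensor inertial motion capture of the torso and
    lower limbs and recognition of seven basic operation postures. Simulates
    body-worn inertial measurement units (IMUs) with realistic noise, filters
    the raw channels with a scalar Kalman filter, performs quaternion
    strapdown integration with heading drift compensation, reconstructs
    skeletal posture through forward kinematics of a hierarchical digital
    human model, exports BVH motion files, builds sliding-window feature
    datasets, and trains a bidirectional LSTM classifier (implemented in
    'RcppArmadillo') to recognize operation postures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
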