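Package: imumocap
Title: Self-Calibrating Lower-Body Inertial Motion Capture by Factor-Graph Smoothing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Magnetometer-free estimation of lower-body skeletal kinematics
    from seven body-worn inertial measurement units (lumbar, thighs, shanks,
    feet). Formulates a batch maximum a posteriori smoothing problem as a
    factor graph combining on-manifold IMU preintegration with biomechanical
    constraints (knee pseudo-hinge kinematics, constrained joint centers,
    knee-axis/segment angle priors, population anthropometry, segment length
    windows and cross-leg length discrepancy), solves it by sparse
    Levenberg-Marquardt, and derives International Society of Biomechanics
    convention knee angles via the Grood-Suntay joint coordinate system.
    Includes a kinematic-chain IMU simulator with analytic ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    data.table,
    jsonlite,
    yaml,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
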