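Package: myotorque
Title: EMG-Driven Knee Joint Torque Estimation with Neuromusculoskeletal,
    Neural-Network and Hybrid Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates sagittal knee joint torque from surface electromyography
    (EMG) of four knee-spanning muscles (rectus femoris, vastus lateralis,
    biceps femoris, semitendinosus) for myoelectric prosthesis control in
    non-weight-bearing tasks. Implements three estimation frameworks: an
    EMG-driven Hill-type neuromusculoskeletal model with activation dynamics,
    tendon-fiber equilibrium and Bayesian (tree-structured Parzen estimator)
    calibration; a convolutional-recurrent (CNN-LSTM) regressor on windowed
    EMG envelopes with architecture search; and a hybrid estimator in which a
    CNN predicts per-muscle activations that drive a simplified contraction
    model. Includes EMG envelope preprocessing (zero-lag Butterworth
    filtering, MVC normalization, windowing), a surrogate muscle-tendon
    geometry model, an NRMSE-based multi-day evaluation harness, and a seeded
    synthetic generator of the non-weight-bearing stool protocol with
    day-to-day drift so all pipelines can be exercised without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
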