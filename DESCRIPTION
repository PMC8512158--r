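Package: beltgait
Title: Capacitive Stretch-Belt Calibration and Cross-Modal Muscle-Activity
    Modelling During Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for a capacitive stretch-sensor belt worn on
    the thigh together with surface electromyography (EMG) and vertical
    ground reaction force (GRF) recordings. Provides quadratic
    capacitance-to-length calibration of the belt sensor, the standard EMG
    envelope chain (high-pass, full-wave rectification, low-pass, MVC
    normalization), gait-cycle segmentation from vertical GRF with
    time-normalization to a percent-gait-cycle grid, between-cycle
    variability statistics, and a quadratic cross-modal regression of belt
    circumference on five thigh-muscle activities evaluated by RMSE,
    ordinary least-squares agreement and ICC(2,1). A seed-reproducible
    synthetic multimodal session generator emulates co-contraction, passive
    knee flexion, walking, running and squatting protocols with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
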