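Package: sigmaglove
Title: Scratch Detection from Sensorised-Glove Stretch and Accelerometer Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting scratching in wearable-glove recordings for
    atopic dermatitis research. A glove instrumented with five microtubular
    stretch sensors (one per finger, resistance change in milliohms) and a
    palm-mounted three-axis accelerometer is sampled at 20 Hz; scratching
    appears as 3-8 Hz oscillations on the stretch channels (finger-dominant)
    or on the accelerometer with sustained finger-bend offsets
    (arm-dominant). The package provides a labelled synthetic-signal
    generator emulating these signatures, the dual-path signal processing
    (high-pass Butterworth filtering, strided moving average, 10 milliohm
    bend thresholding) that turns 8 raw channels into 13 processed channels,
    causal sliding-window segmentation with median window labelling, a
    CNN-LSTM window classifier implemented natively together with a
    deterministic spectral rule baseline, and window- and event-level
    evaluation with NA-aware cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
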