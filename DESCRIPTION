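Package: akfvitals
Title: Adaptive Kalman Filtering of Multichannel Cardiorespiratory Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Real-time-capable separation of multichannel non-contact
    vital-sign recordings (e.g. magnetic induction sensors) into per-channel
    baseline offsets, one shared respiratory signal and one shared cardiac
    signal, using a seven-state time-varying Kalman filter. Measurement and
    process noise covariances, the sensor-fusion measurement matrix and the
    harmonic-oscillator model frequencies are adapted online from the data;
    respiration and heart rates are estimated by peak detection on the
    filtered states and fed back into the state-transition matrix. Includes
    the non-adaptive baseline filter, a synthetic cardiorespiratory session
    generator with ground truth, evaluation metrics, a spectrum-based
    reference rate estimator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
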