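Package: deadtime
Title: Paralyzable Dead-Time Correction and Estimation for Gamma Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form dead-time correction for paralyzable gamma
    detectors via the principal branch of the Lambert W function, together
    with the standard procedures for estimating the resolving time tau:
    the dual (and triple) source method, the "graphical" log-linear fit of
    a decaying source, and the maximum-count-rate method.  Includes the
    energy-window dead-time relation tau_EW = tau_OW / w_f^eta, window
    fraction (pile-up) diagnostics, a synthetic counting-experiment
    simulator with Poisson noise for validating every estimator without
    camera data, delimited text I/O for timed count measurements, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
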