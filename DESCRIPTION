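Package: virtualgate
Title: Camera-Based Virtual Photoelectric Timing Gates for Sprint Timing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a camera-based virtual photoelectric barrier for
    timing flying sprints. A narrow image region acts as a timing gate: the
    mean squared error (MSE) between consecutive frames is compared against a
    sensitivity threshold plus a calibrated noise floor, emulating a light-beam
    photocell. Includes multi-region (dual-beam style) barriers, noise-floor
    calibration from static scenes, Cristian-style clock-offset estimation
    between the controller and gate devices from simulated ping round-trips,
    assembly of gate triggers into timed runs, a synthetic scene generator with
    known ground-truth crossing times, and Bland-Altman agreement statistics
    for method-comparison studies of timing systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
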