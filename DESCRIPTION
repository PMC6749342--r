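Package: pida
Title: Pre-Impact Detection of Tripping from Lower-Limb Elevation Angles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pre-impact detection of loss of balance during walking from a
    single wearable-sensor channel. A pool of adaptive oscillators
    phase-locks to the quasi-periodic elevation angle of a lower-limb
    segment and emits a zero-lag prediction; an adaptive threshold-based
    detector monitors the prediction error through a sliding window and
    signals a lack of balance after a run of consecutive out-of-band
    samples. Includes a seeded synthetic gait generator, two-stage tuning
    over learning-gain and detector grids, evaluation in terms of mean
    detection time and false alarms, CSV/JSON interchange,
    cross-correlation record synchronisation, Welch spectra and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
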