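Package: semgdecode
Title: Decoding Finger Kinematics and Gestures from Surface EMG Electrode Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for decoding continuous finger joint
    angles and discrete hand gestures from 16-channel surface
    electromyography (sEMG) recorded with a 4x4 electrode grid. Provides a
    synthetic session simulator that emulates a cued gesture-repetition
    acquisition protocol (envelope-modulated band-limited sEMG with line
    interference, synchronized joint-angle tracks, gesture annotations),
    signal preprocessing (notch and Butterworth high-pass filtering,
    Savitzky-Golay smoothing, z-score normalization, median-deviation
    outlier rejection), sliding-window grid tensorization, a factorized
    spatio-temporal transformer regressor mapping sEMG windows to 16 joint
    angles, a downstream extremely-randomized-trees gesture classifier, and
    an evaluation battery (normalized joint errors, confusion matrices,
    setting correlations, paired tests, inter-onset-interval statistics and
    classical EMG signal features).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
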