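Package: facetouch
Title: Face-Touch Detection from Smartwatch Inertial and Magnetic Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline toolkit for wrist-worn face-touch detection. Implements
    two streaming detectors for time-stamped smartwatch sensor streams: a
    magnetometer-based detector that senses the virtual magnetic barrier of a
    small permanent-magnet necklace through an adaptive z-score background
    model, and an accelerometer-only detector based on a pitch-rate slope
    majority vote. Both are gated by a roll/pitch wrist-orientation classifier
    derived from the gravity vector. A physics-based simulator (point-dipole
    magnet superposition, scripted minimum-jerk wrist trajectories, sensor
    noise) generates labelled synthetic streams for face-touch gestures and
    confounding activities of daily living, and an evaluation layer segments
    alert events, classifies touch attempts versus happened contacts, and
    runs the accompanying statistical battery (paired t-tests, Shapiro-Wilk
    gating with square-root transform, post-hoc power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
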