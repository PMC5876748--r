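Package: gaitphase
Title: Four-Phase Gait Partitioning from Foot-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of walking trials into the four gait phases
    (loading response, flat foot, pre-swing, swing) from foot-mounted
    inertial sensors. Implements a gyroscope stasis-threshold detector, an
    accelerometer turning/inflection-point detector, and scalar continuous
    hidden Markov model segmenters with subject-specific or cross-subject
    (control-group) training via Baum-Welch and Viterbi decoding.
    Footswitch signals provide the reference phase sequence. Includes
    transition-level accuracy metrics (sensitivity, specificity, goodness
    index with a 60 ms tolerance window), per-phase percentage errors, the
    Gait Phases Quality Index (GPQI) with test-retest reliability
    statistics (ICC(3,k), minimal detectable change), ROC/AUC group
    discrimination, and a seeded synthetic gait generator with exact
    ground-truth events for healthy and parkinsonian-like presets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
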