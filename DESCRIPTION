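Package: coregload
Title: Co-Registered EEG and Eye-Tracking Analysis of Cognitive Load
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing co-registered EEG and eye-tracking
    recordings as physiological proxies of cognitive load. Provides stream
    synchronization via shared trigger events, adaptive velocity-based
    saccade and fixation detection with area-of-interest labeling, blink
    interpolation for pupillometry, FIR filtering, ICA-based ocular
    artifact removal, average re-referencing, stimulus-locked and
    fixation-related epoching with amplitude-based rejection, sliding
    Hanning-window band power and ERD/ERS percent change against global
    condition baselines, and a statistical layer with repeated-measures
    ANOVA (Greenhouse-Geisser correction), Holm post hocs, sign-flip
    permutation tests with FDR over electrodes, repeated-measures
    correlation, and within-subject standard errors. Includes a synthetic
    session generator with ground truth so every stage is testable
    without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    matrixStats
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
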