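Package: lrpdetect
Title: Sliding-Window Detection of Movement Intention from the Lateralized Readiness Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asynchronous detection of movement intention from
    multichannel EEG using the lateralized readiness potential (LRP). Implements
    a seeded generator of synthetic reach-to-target study datasets (EEG, 3-D
    hand-marker motion, event tables, ground-truth onsets), kinematic estimation
    of physical movement onset from motion-capture trajectories, reduced
    left-hemisphere and standard 10-20 channel montages, a sliding-window
    feature pipeline (per-window standardization, anti-aliased decimation, FFT
    band-pass, xDAWN spatial filtering, Gaussian feature normalization), an
    L1-regularized linear support-vector classifier with Platt probability
    calibration, change-point relabeling with balanced-accuracy scoring, ERP
    epoching and grand averages, and leave-one-set-out evaluation of cross-task
    transfer from bilateral to unilateral movements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
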