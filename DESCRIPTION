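Package: sleeploop
Title: Closed-Loop Slow-Oscillation Stimulation Analysis for Intracranial Sleep Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis stack for slow-oscillation-targeted
    closed-loop stimulation studies of human sleep. Provides a synthetic
    intracranial EEG generator with ground-truth event annotations, line-noise
    removal and interictal-discharge masking, NREM sleep scoring by Gaussian
    mixture clustering of slow-wave and sigma band power, single-event
    detection of slow waves, sleep spindles and medial-temporal-lobe ripples,
    an offline simulation of a real-time slow-wave-triggered stimulation
    controller with post-hoc timing audit, stimulation-locked time-frequency
    and event-probability analyses with matched sham events, spike-field phase
    locking by cosine fits of spike-phase histograms with Rayleigh gating and
    shuffling validations, oscillation co-occurrence measures, and overnight
    paired-associate memory and vigilance scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
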