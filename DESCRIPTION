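Package: fatigueEEG
Title: EEG Driving-Fatigue Detection Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying driver fatigue from multichannel EEG.
    Generates synthetic 32-channel EEG with state-dependent band power
    (elevated theta/delta under fatigue, prominent alpha/beta when awake),
    preprocesses recordings (downsampling, zero-phase bandpass filtering,
    fixed-length epoching), denoises single channels by wavelet thresholding
    with hard, soft and improved-soft rules, extracts features by short-time
    Fourier band power spectra and by empirical mode decomposition combined
    with energy spectral density, and classifies epochs with extreme learning
    machines (ELM), hierarchical ELM, particle-swarm-optimized hierarchical
    ELM, and KNN/SVM baselines under a leave-one-subject-out harness with
    paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    class,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
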