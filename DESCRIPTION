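Package: ptcoherence
Title: Automated Detection of Objective Pulsatile Tinnitus from Ear-Canal
    Sound and Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects pulse-synchronous (objective pulsatile tinnitus) sound
    in ear-canal microphone recordings by computing the magnitude-squared
    coherence, at the heart rate, between octave-band Hilbert envelopes of
    the calibrated sound and a simultaneously recorded fingertip
    photoplethysmogram (the Pulsatile-Tinnitus Coherence Index, PTCI).
    Includes beat-by-beat artifact rejection keyed on the PPG systolic
    peaks, an evaluation layer (majority vote over blinded observers,
    Fleiss kappa, ROC/AUC, sensitivity/specificity tables), a synthetic
    paired-recording generator with full ground truth for validation
    without clinical data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
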