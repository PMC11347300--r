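Package: pupilgate
Title: Event-Related Pupillary Response Biometrics with RSVP Oddball Paradigms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating biometric authentication systems
    based on event-related potentials (ERP) and event-related pupillary
    responses (ErPR) elicited by rapid serial visual presentation (RSVP)
    oddball tasks. Provides RSVP stimulus scheduling, a synthetic cohort
    simulator with known ground truth, EEG and pupil preprocessing (resampling,
    zero-phase Butterworth band-pass filtering, pupil-size-change computation,
    epoching, baseline correction, averaging), peak-to-peak amplitude and
    latency feature extraction in the P3a, P3b and LPP windows, paired
    statistics with effect sizes and Bland-Altman agreement, and classifier
    evaluation with stratified cross-validation reporting accuracy, AUC, false
    acceptance and false rejection rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    MASS,
    e1071,
    pROC,
    jsonlite,
    yaml,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
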