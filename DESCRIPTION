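Package: gaitEEG
Title: Single-Trial EEG Decoding of Gait Speed Changes During Treadmill Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a single-trial EEG analysis pipeline
    that detects gait speed changes (constant-speed vs change-speed walking) on
    a treadmill. Includes a synthetic-EEG generator with a 4-shell spherical
    forward model (cortical mu/beta event-related desynchronization sources,
    blink, EMG-burst, step-locked and 1/f background sources), FIR band-pass
    preprocessing with automatic order selection, two-pass ICA with
    probability-based segment rejection, equivalent-current-dipole fitting and
    dipole-based component rejection, Morlet wavelet time-frequency features,
    sparse-logistic-regression component selection with the scree acceleration
    factor, PCA plus sparse logistic classification, cross-validated Cohen's
    kappa with the adjusted-Wald lower bound, pseudo-online sliding-window
    decoding with all-or-nothing ROC, cross-subject component clustering and
    artifact quality-control analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    MASS,
    utils,
    signal,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
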