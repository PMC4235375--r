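Package: hybridbci
Title: Hybrid fNIRS-EEG Decoding of Auditory and Visual Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for passive brain-computer
    interfacing with simultaneous functional near-infrared spectroscopy
    (fNIRS) and electroencephalography (EEG). Provides a synthetic
    multimodal session generator with a randomized audio/visual block
    design, the optical preprocessing chain (AC normalization, cardiac
    pulse correction, median filtering and downsampling, modified
    Beer-Lambert conversion to oxy- and deoxyhaemoglobin, common average
    referencing), EEG preprocessing (zero-phase FIR band-pass, ICA-based
    eye-blink removal, prestimulus baseline correction), four single-trial
    feature extractors (haemoglobin slope, Welch band power, downsampled
    event-related potentials), shrinkage-regularized linear discriminant
    and linear support vector classifiers with probabilistic decision
    fusion, nested leave-one-trial-out and leave-one-subject-out
    cross-validation, continuous (non stimulus-locked) decoding, binomial
    chance bounds, and correlation-based feature rankings with Friedman
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
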