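Package: p300bmi
Title: P300 Brain-Machine Interface Pipeline for Hand-Orthosis Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline, simulator-driven implementation of a P300-based
    brain-machine interface for selecting hand-orthosis movements. Provides
    the full signal chain from multichannel EEG to online option selection:
    FIR band-pass preprocessing with amplitude/variance/power-ratio artifact
    validation, canonical-correlation spatial filtering of event-related
    potentials, stepwise-selected regularized linear discriminant
    classification of single flash epochs, and an evidence-threshold
    interface controller. Includes the calibration-session scheduler, a
    synthetic-EEG session generator (oddball-locked evoked responses on 1/f
    background noise with artifact bursts), kernel-density baseline tests
    for ERP significance, and performance evaluation via stratified
    cross-validation, permutation tests, and Wolpaw information transfer
    rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
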