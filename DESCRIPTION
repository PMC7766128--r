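Package: gaitBCI
Title: Motor-Imagery Hybrid Brain-Computer Interface Controller for a
    Lower-Limb Exoskeleton
Version: 0.1.0
Authors@R:
    person("BCI", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, decoding and control stack for an asynchronous
    motor-imagery brain-computer interface that drives a lower-limb
    exoskeleton through a sit/stand/gait finite-state machine.  Implements
    filter-bank common spatial patterns (FBCSP) with mutual-information
    based best individual feature (MIBIF) selection and a linear
    maximum-margin classifier; a triple eye-blink (TEB) brain switch
    detected from prefrontal EEG; command stack buffers with 1:3
    fill/empty dynamics; a seeded synthetic EEG generator
    (sensorimotor-rhythm ERD, pink background noise, line noise, blink
    artifacts); EDF input/output; and the evaluation toolbox (bootstrap
    offline accuracy, TPR/FPR/ACC, information transfer rate, Fisher-ratio
    topography, ERSP).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
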