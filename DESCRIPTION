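Package: vorpulse
Title: Biomimetic Pulse-Rate Encoding and Vestibulo-Ocular Reflex Modelling
    for Vestibular Prostheses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating head-velocity-to-pulse-rate
    mappings for vestibular prostheses. Implements linear-nonlinear cascade
    encoders that mimic regular and irregular semicircular-canal afferent
    dynamics, a control-systems forward model of the prosthesis-driven
    vestibulo-ocular reflex (velocity storage, pathway delay, oculomotor
    plant, stimulation efficacy, peripheral adaptation and central
    depression), a synthetic eye-movement recording generator with ground
    truth, a slow-phase eye-movement analysis pipeline (desaccading,
    per-cycle sinusoidal fits, bootstrap standard errors, transient
    metrics), and frequency-domain system identification (rational
    transfer-function fits, variance accounted for, stimulation-efficacy
    estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
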