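Package: adckinetics
Title: Kinetic Modeling of Antibody-Drug Conjugate Conjugation Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mechanistic reaction-kinetics modeling of maleimide-cysteine
    conjugation reactions used to manufacture antibody-drug conjugates
    (ADCs). Simulates site-specific (DAR 2) and interchain-disulfide
    (DAR 8) conjugation of payloads to antibody heavy and light chains in
    batch and fed-batch mode, estimates conjugation rate constants from
    chain-level kinetic time series by nonlinear least squares, assesses
    parameter identifiability by local one-at-a-time sensitivity analysis,
    selects among model candidates using parameter uncertainty and
    leave-one-run-out cross-validation errors, and screens initial mAb
    concentration and molar drug excess in silico for final drug-to-antibody
    ratio, residual free payload and reaction time. Includes a synthetic
    kinetic-data generator emulating the reducing RP-UHPLC observation model
    so the whole pipeline is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
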