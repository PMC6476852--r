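Package: windkick
Title: Kicked-Windkessel Model of Cardiorespiratory Blood-Pressure Buffering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-compartment ("kicked Windkessel") model of
    arterial blood-pressure dynamics driven by an integrate-and-fire cardiac
    oscillator under respiration-gated, phase-sensitive neural control of
    heart rate. Provides per-beat systolic, diastolic and mean pressure
    extraction, relative fluctuation-magnitude analysis against a control-off
    reference, and parameter sweeps over the neural delay and amplitude that
    locate effective-buffering and paradoxical-enhancement regimes of
    respiratory sinus arrhythmia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    withr
Config/testthat/edition: 3
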