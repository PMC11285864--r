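Package: pulsesham
Title: Sham-Controlled Magnetic Pulse Design and Migratory Trait Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and verification of sham-controlled magnetic-pulse
    experiments for magnetoreception research, with the statistical battery
    used to analyse free-flight migratory behaviour. Simulates
    capacitor-discharge pulse-coil circuits in closed form, derives field and
    Faraday induced-voltage waveforms, designs sham pulses that match the
    treatment's onset dB/dt while capping the peak field below magnetite
    switching thresholds, audits pulser devices for control adequacy, and
    compares treatment and sham groups on five migratory traits with a
    continuity-corrected chi-square test, a tie-exact Wilcoxon rank sum test,
    the Rayleigh test and the Mardia-Watson-Wheeler uniform-scores test with
    repeated random tie breaking. A synthetic cohort generator and Monte
    Carlo harness support type-I-error calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
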