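Package: vbephys
Title: Simulation and Analysis of Thalamic Relay Neuron Patch-Clamp Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing burst-firing, T-type calcium currents and
    the hyperpolarization-activated cation current (Ih) in thalamocortical relay
    neurons. Provides a single-compartment conductance-based model of a
    ventrobasal (VB) neuron with T-type, HCN, high-voltage-activated calcium,
    leak and spiking conductances that runs standard current-clamp and
    voltage-clamp step protocols; current-clamp analyses (spike and rebound
    burst detection, burst threshold over a protocol ladder, input resistance,
    sag, burst morphology, tonic firing, input-output curves); voltage-clamp
    pipelines (whole-cell capacitance from the 5-mV transient, offline leak
    correction, current-density I-V curves, pre-pulse separation of T-type from
    high-voltage-activated calcium currents, blocker-subtracted Ih tail-current
    activation with Boltzmann fits, Hill dose-response fits); a generalized
    Henderson liquid-junction-potential calculator; and cohort-level group
    statistics for two-strain comparison studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
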