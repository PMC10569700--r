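Package: hhpatch
Title: Species-Specific Hodgkin-Huxley Channel Models in a Nucleated-Patch Compartment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Hodgkin-Huxley conductance models of human and mouse somatic
    voltage-gated Na+ and K+ channels, a single-compartment "nucleated patch"
    simulator with current-clamp, voltage-clamp and AP-clamp modes, and the
    downstream analyses that link channel biophysics to action-potential
    stability and input-output bandwidth: voltage-clamp protocol batteries
    with exponential/Boltzmann curve fitting, CMA-ES channel-model fitting,
    Powell conductance-density fitting to AP waveform features, AP-train
    stability metrics, and sinusoid-plus-noise phase-locking (M/R) analysis
    with cutoff-frequency estimation. A seeded synthetic voltage-clamp data
    generator emulates noisy nucleated-patch recordings (leak, capacitive
    transients, P/-5 subtraction sweeps) so the whole pipeline can be
    exercised and validated against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    minpack.lm,
    rlang,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    dplyr,
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
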