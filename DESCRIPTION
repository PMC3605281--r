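Package: lognet
Title: Training Logic Models of Protein Signaling Networks to Perturbation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds context-specific logic models of protein signaling
    networks by fitting sub-networks of a prior knowledge network (SIF
    format) to perturbation (phospho)proteomic data (MIDAS format). The
    prior network is compressed and expanded into a scaffold of candidate
    logic gates, and a genetic algorithm selects the sub-model that best
    balances fit to data against model size. Five logic formalisms share
    the pipeline: Boolean steady state, Boolean with two pseudo-steady
    states, discrete-time Boolean simulation with a trainable time-scale
    factor, constrained fuzzy logic with normalized Hill transfer
    functions, and logic-derived ordinary differential equations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    deSolve,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
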