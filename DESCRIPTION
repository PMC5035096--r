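Package: neuroscreen
Title: Semi-Automated Screening of Multi-Compartment Conductance-Based Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and screens populations of multi-compartment conductance-based
    interneuron models. Reads SWC morphologies, discretizes branched cables into
    isopotential compartments, attaches Hodgkin-Huxley style voltage-gated channels
    with configurable spatial distributions (uniform, soma-only, Boltzmann proximal
    fall-off), and integrates the branched-cable equations under current-clamp,
    noise, and synaptic point-process stimulation with an implicit tree solver.
    Extracts electrophysiological signature features from voltage traces (sag,
    depolarization height, spike shape, depolarization block), applies criterion
    based model elimination, ranks surviving models by a normalized distance to
    reference measurements, and visualizes conductance parameter spaces by
    dimensional stacking. Downstream analyses cover passive electrotonic
    attenuation, backpropagating action potential amplitude profiles, and
    synaptic threshold-weight scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
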