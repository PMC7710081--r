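Package: tactopop
Title: Simulation and Synaptic Readout of First-Order Tactile Neuron Populations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data-driven spiking models of human fast-adapting type 1 (FA-1)
    tactile neurons with spatially complex receptive fields, genetic-algorithm
    fitting of the models to multi-trial spike responses to moving oriented
    edges, simulation of the first-order neuronal population innervating a
    fingertip-sized skin patch, and two-unit classifiers that discriminate
    edge orientation by synaptic (postsynaptic-potential) integration of the
    population activity. Includes a synthetic-recording generator so the full
    fitting and discrimination pipeline is testable without microneurography
    data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
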