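Package: rotafret
Title: Single-Molecule FRET Analysis of Serine Recombinase Subunit Rotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule FRET trajectories of
    serine recombinase synaptic complexes undergoing subunit rotation.
    Provides a Gillespie simulator for the four-state recombination scheme
    (ligated/cleaved, non-recombinant/recombinant), camera-style rendering of
    donor/acceptor intensity traces with photobleaching, Gaussian-emission
    hidden Markov model idealization, transition density plot clustering with
    a constrained K(K-1)-component mixture and BIC model selection, dwell-time
    kinetics via cumulative-distribution exponential fits with bootstrap
    errors and weighted-average rate constants, Forster-equation
    distance/efficiency conversion, and accessible-volume dye simulations with
    a rigid-body subunit-rotation scan.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    minpack.lm,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
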