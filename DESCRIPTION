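Package: gatekin
Title: Magnesium-Dependent Protein-DNA Gate Kinetics in Type IA Topoisomerases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic modelling and single-molecule analysis of the
    magnesium-regulated protein-DNA gate of type IA topoisomerases. Implements
    an eight-state salt-bridge-switch continuous-time Markov model of gate
    opening and closing, exact stochastic (Gillespie) simulation of gate
    trajectories, synthesis of magnetic-tweezers extension traces and dwell-time
    datasets, two-state Gaussian hidden-Markov trace idealization with dwell
    extraction, maximum-likelihood and biphasic magnesium-dependence rate
    inference with bootstrap uncertainty, and salt-bridge/gate-coordinate
    analysis of multi-model PDB coordinate trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    minpack.lm,
    lhs,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
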