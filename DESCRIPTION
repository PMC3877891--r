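Package: raftperm
Title: Quantitative Analysis of Raft-Targeting Membrane Permeabilization
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for quantifying how a raft-targeting cyclodepsipeptide
    binds to and permeabilizes cell membranes. Implements Number and
    Brightness (N&B) fluctuation analysis of confocal image stacks with
    registration and stack quality control, seeded-watershed membrane
    segmentation and bright-spot counting, Hill dose-response fitting, a
    mechanistic oligomer-threshold permeabilization model that reproduces
    cooperative killing from non-cooperative binding, a two-compartment
    uptake-kinetics model with an initial-slope estimator of membrane
    binding, fluorescence anisotropy and Laurdan generalized polarization
    calculators, and Fisher z-transform correlation confidence intervals.
    A synthetic-data generator with known ground truth makes every analysis
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
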