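Package: serovolt
Title: Simulation and Analysis of Serotonin and Dopamine Voltammetry in a
    Parkinsonism Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse fast-scan cyclic voltammetry (FSCV)
    and fast-scan controlled-adsorption voltammetry (FSCAV) measurements of
    hippocampal serotonin and striatal dopamine in an MPTP mouse model of
    Parkinsonism. Provides synthetic color-plot and ambient-serotonin
    generators, two-uptake Michaelis-Menten reuptake kinetics with a
    forward-sensitivity gradient-descent fitter, a convolutional neural
    network that regresses the serotonin:dopamine ratio of a color plot from
    convex-mixture augmented training data (with randomisation-based feature
    importance), and a reduced ordinary-differential-equation model of
    serotonin-dopamine interaction under nigral degeneration, SSRI dosing and
    levodopa.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    minpack.lm,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
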