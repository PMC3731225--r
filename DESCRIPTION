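Package: grnland
Title: Potential Landscapes and Kinetic Paths for Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the epigenetic (Waddington) landscape of signed
    gene regulatory networks modelled with additive Hill kinetics. Locates
    attractors (cell states) by multi-start integration, builds landscapes
    U = -ln P either by Gaussian moment closure under a self-consistent mean
    field or by histogramming Langevin trajectories, computes steady-state
    probability flux, grid barrier heights via minimax saddles, mean first
    passage times, dominant transition paths by Onsager-Machlup action
    minimisation, discretized cell-state transition graphs, activation
    annealing/hysteresis experiments, and global sensitivity analysis of
    regulatory links and genes. Ships a reconstruction of a 52-gene human
    stem-cell network together with small synthetic fixtures and analytic
    double-well oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    igraph,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
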