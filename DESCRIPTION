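Package: epichain
Title: Cell-Chain Mechanics of an Epithelial Sheet and Its Free-Boundary Continuum Limit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a one-dimensional chain of mechanically interacting
    epithelial cells (overdamped spring dynamics with linear, Hertz or cubic
    force laws, and stochastic length-dependent proliferation) and solves the
    corresponding coarse-grained free-boundary nonlinear diffusion model on a
    fixed domain via a Lagrangian transformation, using an implicit finite
    difference scheme with Picard iteration. Includes harnesses that compare
    the leading-edge position and cell number of the cell-based model against
    the continuum model, ensemble averaging over stochastic realisations, and
    a convergence study in the cell number.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
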