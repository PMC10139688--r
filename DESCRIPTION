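Package: morphosim
Title: Cell-Based Stochastic Simulation of Morphogen Gradient Precision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates steady-state morphogen gradients on one-dimensional
    cellular tissue domains with cell-to-cell variability in cell areas and
    in the kinetic parameters of morphogen production, decay and transport.
    Supports linear and non-linear (self-enhanced) morphogen decay, explicit
    source domains as well as flux and Dirichlet source boundary conditions,
    and quantifies patterning precision through the positional error of
    threshold-based (French flag) readout positions across Monte-Carlo
    ensembles, with bootstrap standard errors. Includes closed-form
    exponential and shifted power-law reference gradients, a conservative
    finite-volume boundary-value solver with per-cell coefficients, sweep
    presets over decay exponents, noise levels, cell sizes and source
    strengths, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
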