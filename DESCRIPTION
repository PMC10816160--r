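Package: biosorb
Title: Statistical-Physics Modelling of Heavy-Metal Biosorption
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing batch heavy-metal biosorption experiments on
    lignocellulosic and alginate adsorbents. Fits the single-layer
    statistical-physics isotherm coupled to a real-gas (van der Waals)
    description of the solute (SLMRG) by multi-start nonlinear least squares,
    fits pseudo-first-order, pseudo-second-order and Weber-Morris
    intra-particle diffusion kinetic models by both linearized and nonlinear
    routes, performs van't Hoff thermodynamic analysis with
    physisorption/chemisorption classification, determines the point of zero
    charge from pH-drift titrations, and post-processes quantum-chemical
    outputs into conceptual-DFT reactivity descriptors, COSMO-RS sigma-profile
    region areas and QTAIM bond-critical-point classifications. Includes
    seeded synthetic-data generators so every pipeline stage is testable
    without external measurements.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
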