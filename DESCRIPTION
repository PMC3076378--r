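Package: tumorvasc
Title: Multiscale Simulation of Vascular Tumour Growth in Three Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An individual-based multiscale model of vascular tumour growth
    on a 3D lattice. Couples Poiseuille blood flow with haematocrit transport
    through a dynamic vessel network, structural adaptation and pruning of
    vessel radii, VEGF-driven angiogenic sprouting with chemotactic tip-cell
    migration and anastomosis, quasi-steady finite-difference
    reaction-diffusion of oxygen and VEGF, and oxygen-dependent cell-cycle,
    p53 and quiescence dynamics of individual normal and cancer cells.
    Supports reflecting and periodic boundary conditions, tiled multi-vessel
    tissue units, import of experimentally derived vascular graphs, and an
    experiment layer for ensemble statistics with bootstrap confidence
    intervals and tumour-elimination probability extrapolation across domain
    sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
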