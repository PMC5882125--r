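Package: auxinpin
Title: Auxin-PIN1 Phyllotaxis Models: Lattice Simulation and Linear Stability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Cell-lattice models of auxin maximum formation at the shoot
    meristem, built on the mutual interaction between auxin and its efflux
    carrier PIN1. Implements the classical up-the-gradient model without
    extracellular space (Model O), its extension with explicit apoplast
    compartments and influx carriers (Model A, including symplast and
    apoplast auxin diffusion), and a family of models with a diffusible
    mediator molecule X feeding back on auxin-PIN1 dynamics (Models B1-B6,
    with simple, symplast, or apoplast X diffusion). Provides analytic
    equilibria, explicit Euler integration on periodic 1D rings and 2D
    hexagonal tori, analytic dispersion relations with a brute-force
    circulant-Jacobian oracle, dominant-wavelength and cluster-size pattern
    metrics, parameter-plane sweep drivers, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
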