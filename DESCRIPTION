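Package: npcbarrier
Title: Entropic Barrier Free Energies of the Nuclear Pore Complex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Field-theoretic free-energy calculations for cargo transport
    through the nuclear pore complex (NPC). FG-nucleoporins are modelled as
    continuous Gaussian chains tethered to the wall of a cylindrical pore;
    the chain propagator is obtained by solving the modified diffusion
    equation with backward-Euler contour stepping on a finite-volume spatial
    discretization (full 3-D grid or an axisymmetric fast path). The package
    computes insertion free-energy differences for inert and attractive
    cargoes, mean segment-density maps, critical transportable cargo
    diameters, mean insertion forces, and the effect of binding-spot
    geometry (uniform spherical caps and Kent-distributed spot patterns),
    together with closed-form and Monte Carlo chain-sampling oracles used
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
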