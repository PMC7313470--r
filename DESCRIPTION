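Package: retmech
Title: Tensile Mechanics of Soft Tissue on a Two-Scaffold Stretcher
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tensile tests of soft neural tissue (adult
    retina) mounted across two rigid scaffolds. Calibrates a glass-fiber
    force sensor by Hooke's law, segments force-distance curves into a
    nonlinear toe region plus four deformation regimes (linear rise, constant
    force plateau, steeper rise, second plateau), extracts elastic constants
    and yield forces, and identifies the tissue's effective Young's modulus
    by inverse fitting of a three-dimensional small-strain linear-elasticity
    finite-element model of the stretcher geometry with a near-incompressible
    tissue layer. Includes a seeded synthetic-experiment generator so that
    every stage is testable end to end without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
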