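Package: stomech
Title: Finite-Element Mechanics of Stomatal Guard Cells and AFM Stiffness Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the turgor-driven mechanics of a stomatal guard-cell pair as a
    pressurized pair of hollow deformed tori with a transversely isotropic
    Veronda-Westmann wall, solved by a total-Lagrangian finite-element method with
    follower pressure loads and adaptive load incrementation. Computes pore aperture,
    pore area and stomatal aspect ratio as functions of turgor pressure, and effective
    (von Mises) stress and effective Lagrange strain fields. Also implements an atomic
    force microscopy (AFM) force-map pipeline that converts grids of force-indentation
    curves into apparent Young's modulus maps via pyramidal-indenter Hertzian fits,
    together with seeded synthetic force-map and benchmark-mesh generators for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
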