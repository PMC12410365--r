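Package: rbcflow
Title: Cell-Resolved Red Blood Cell Deformation and Shear-Damage Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale, cell-resolved modelling of red blood cell (RBC)
    mechanical damage in high-shear flows. Provides a spectral
    (spherical-harmonic) boundary-integral solver for a deformable RBC
    membrane governed by the Skalak in-plane law and the Helfrich bending
    energy, driven by Lagrangian velocity-gradient histories; massless
    particle tracking on tetrahedral meshes with flux-weighted inlet
    seeding and wall reflection; analytic and stored time-periodic
    background flows with Fourier temporal reconstruction and L2 gradient
    recovery; and ensemble damage statistics (strain PDFs, threshold
    classification, exposure counting, cell damage index) used to compare
    flow geometries such as surgical shunts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
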