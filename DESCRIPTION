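Package: stiffmatch
Title: Stiffness-Matched Porous Superelastic NiTi Fixation Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and desk-scale evaluation of stiffness-matched porous
    superelastic NiTi mandibular fixation hardware. Implements a
    phase-diagram superelastic constitutive model for NiTi (1D and
    small-strain 3D), exact and voxelized geometry of the
    three-orthogonal-cylinder pore unit cell, a voxel hexahedral finite
    element solver with tie and compression-only contact interfaces,
    uniaxial-stress homogenization of unit cells into equivalent
    stress-strain curves, a porosity selection loop that matches a target
    bone modulus with local-stress safety checking, and a simplified
    parametric mandibular-reconstruction assembly for comparing dense
    Ti-6Al-4V against stiffness-matched porous NiTi plates under bite and
    pretension loads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
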