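Package: aesm
Title: Alpha-Shape Elastic Solid Models for Macromolecular Normal Mode
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds elastic solid models of macromolecules from atomic
    coordinates or cryo-EM density maps. A structure's shape is captured
    as an alpha-shape tetrahedral solid (Delaunay tetrahedralization
    filtered by circumsphere radius), finite-element stiffness and
    consistent mass matrices for isotropic linear elasticity are
    assembled over the tetrahedra, and normal modes are obtained from the
    generalized eigenproblem. Provides B-factor prediction and Young's
    modulus calibration, vibrational spectra and power-law fits,
    conformational-change overlap metrics, linear static response to
    external forces with an indentation-stiffness surrogate for AFM
    calibration, shape-preserving non-uniform coarse-graining by
    layer-wise surface decimation, an anisotropic network model baseline,
    and mesh export to standard finite-element formats.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RSpectra,
    bio3d,
    igraph,
    FNN,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    withr,
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with scipy, on the PATH, for
    Delaunay tetrahedralization (Qhull).
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
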