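Package: paleofract
Title: Image-Based Finite Element Inference of Long-Bone Fracture Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the loading conditions that fractured a
    long bone from volumetric image data. Provides synthetic bone phantom
    generators with known ground truth (cortical shell, concentric cancellous
    density classes, oriented trabecular microstructure, planted fracture
    planes and taphonomic cracks), greyscale segmentation and crack
    classification, mean intercept length fabric tensor analysis with degree
    of anisotropy, density-to-modulus material mapping with volume-weighted
    homogenisation, a linear-static constant-strain tetrahedral finite
    element solver with von Mises and principal stress post-processing, a
    fracture-plane consistency scorer with grid search over candidate loading
    regimes, and the Newtonian force-scaling, body-mass and fall-kinematics
    chain that converts a finite element solution into an impact scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
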