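Package: vasculate
Type: Package
Title: Image-Based One-Dimensional Haemodynamic Simulation of Vascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless toolkit for reduced-order (1D-0D) pulse-wave blood flow
    simulation on vascular networks derived from segmented medical images.
    Covers the full pipeline: topology-preserving skeletonization of binary
    vessel volumes with distance-transform radii, penalized quintic-spline
    centerline smoothing with AIC-selected roughness penalties, a Richtmyer
    Lax-Wendroff solver for the 1D pulse-wave equations closed by an elastic
    tube law and coupled to RCR Windkessel terminals and Young-type stenosis
    elements, wall shear stress and TAWSS post-processing, wall-shear-stress
    homeostasis (constant-WSS) arterial remodeling, and dynamic triangle-mesh
    lumen reconstruction with VTK/PLY export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    igraph,
    jsonlite,
    yaml,
    pracma,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
SystemRequirements: C++17
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
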