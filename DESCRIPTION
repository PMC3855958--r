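Package: myocemm
Title: Multiscale Chemoelectromechanical Simulation of Skeletal Muscle
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator of coupled skeletal-muscle
    electromechanics. Zero-dimensional half-sarcomere models (membrane
    electrophysiology, calcium release, two-state attached crossbridge
    pools) drive action-potential propagation along embedded one-dimensional
    muscle fibers via the monodomain equation with first-order
    reaction-diffusion operator splitting, and couple to a quasi-static,
    incompressible, transversely isotropic hyperelastic continuum
    (Mooney-Rivlin matrix plus fiber reinforcement and an active stress
    scaled by crossbridge occupancy, the force-length relation, and Hill's
    force-velocity relation) discretized with Taylor-Hood hexahedral finite
    elements. A three-rate staggered scheduler links the scales through
    homogenization and interpolation transfer operators on embedded fiber
    meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
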