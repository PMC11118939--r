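Package: lumbarfe
Title: Finite-Element Stability Analysis of an Osteoporotic Lumbar Spine Segment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale nonlinear finite-element simulator of an L2-L4 lumbar
    spine segment under axial compression. Builds a parametric quasi-cylindrical
    geometry (vertebral bodies with cortical shell, endplates and simplified
    posterior elements, intervertebral discs with nucleus, annulus and +/-30
    degree fibre layers, six ligament groups), derives constitutive cards from
    bone-density power laws and Neo-Hookean coefficient relations, and sweeps
    five grades of age-related degeneration (trabecular softening,
    cortical-trabecular debonding, disc degeneration). A total-Lagrangian
    Newton-Raphson solver with hexahedral solids, quadrilateral shells and
    tension-only ligament links computes load capacity, plastic onset,
    disc bulging/shearing/shortening, and buckling/bifurcation stability
    metrics, including linearized buckling from the geometric stiffness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
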