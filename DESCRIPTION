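Package: cartimech
Title: Fibril-Reinforced Poroelastic Finite-Element Analysis of Focal
    Cartilage Defects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale pipeline for quantifying mechanical failure risk
    around focal cartilage defects in an idealized tibial compartment.
    Generates synthetic compartment geometry with depth-dependent
    Benninghoff collagen architecture, solves quasi-static
    displacement-pressure poroelasticity with a fibril-reinforced
    cartilage material and frictionless rigid-indenter contact over a
    two-peak stance-phase load protocol, carves and relocates
    parametric partial-thickness defects at constant normalized
    penetration depth, calibrates bone moduli from CT phantom volumes,
    and evaluates five strain- and stress-based cartilage failure
    criteria around the defect rim.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
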