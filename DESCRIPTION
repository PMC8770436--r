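Package: micromotionfem
Title: Finite-Element Analysis of Micromotion-Induced Brain Strain Around
    Intracortical Probes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the mechanical interaction between an implanted
    intracortical microelectrode and surrounding brain tissue under
    micromotion. Builds graded structured hexahedral meshes of a rectangular
    probe shank embedded in a linear-elastic tissue block, assembles and
    solves the static small-strain elasticity problem with B-bar trilinear
    elements under prescribed tangential displacement, and recovers Von
    Mises equivalent strain fields. Postprocessing reproduces the standard
    comparisons across probe materials and thicknesses: maximum tissue
    strain and its location along the shank, strain normalized to a stiff
    silicon baseline, and strain-decay profiles away from the probe surface,
    together with a monitoring-point mesh-sensitivity protocol and analytic
    verification fixtures (patch test, uniaxial block, Timoshenko
    cantilever, bimaterial bar).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
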