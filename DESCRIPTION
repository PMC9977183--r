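Package: llrmorph
Title: Evolutionary Lines of Least Resistance in Geometric Morphometric Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether a conserved allometric pattern acts as
    an evolutionary line of least resistance in clade-wide 3D landmark data.
    Implements generalized Procrustes superimposition with tangent-space
    projection, multivariate phylogenetic generalized least squares with
    residual-randomization permutation tests, ordinary, phylogenetic and
    phylogenetically aligned component analyses, multivariate Brownian-motion
    rate matrices with morphospace confidence contours, projected-variance
    (evolvability) and eigenvalue-dispersion integration statistics with
    random-vector and random-angle null distributions, and a fully seeded
    synthetic-data generator that emulates the assumed data-generating process
    for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phytools
Config/testthat/edition: 3
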