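Package: angledens
Title: Collective Density Estimation of Protein Backbone Angle Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint nonparametric estimation of many bivariate densities of
    protein backbone angles (Ramachandran (phi,psi) or C-alpha pseudo-angle
    (theta,tau) distributions) through a shared low-rank basis expansion of the
    log-densities. Angular periodicity is handled with tensor products of
    trigonometric B-splines, smoothness with a difference roughness penalty
    whose tuning parameter is updated inside the Newton-Raphson iterations.
    Includes a wrapped-kernel density baseline, symmetrized Kullback-Leibler
    distances between fitted densities, Ward clustering with external
    evaluation (normalized mutual information, adjusted Rand index), backbone
    dihedral and pseudo-angle computation from PDB files, and generators for
    synthetic grouped angular data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    bio3d,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
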