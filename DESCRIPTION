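Package: paleoshape
Title: Phylogenetic Estimation of Ancestral Cranial Shapes from 3D Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for geometric-morphometric and phylogenetic analysis of 3D
    landmark data on dated phylogenies. Provides Generalized Procrustes
    Analysis with bending-energy sliding of curve and surface semilandmarks,
    extraction of the symmetric shape component, thin-plate-spline warping and
    missing-landmark imputation by mirroring and interpolation, maximum
    likelihood ancestral shape estimation under Brownian motion with 95%
    confidence envelopes ("virtual last common ancestors"), multivariate
    phylogenetic signal (Kmult), between-group principal component analyses
    with passive projection of fossils, Euclidean and Procrustes distance
    reports, mesh warping with vertex-wise surface deviation spectra, and a
    synthetic data generator that simulates population mean shapes evolving by
    Brownian motion on a chronogram with within-population variation and
    fossil preservation masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
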