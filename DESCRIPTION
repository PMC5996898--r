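Package: leaftopo
Title: Topological Morphometrics for Leaf Outlines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures leaf shape with a localized persistent-homology
    descriptor: outlines are rasterized as two-dimensional point clouds, a
    Gaussian density estimator is restricted to concentric annulus kernels
    around the centroid, and the Euler characteristic of the superlevel-set
    filtration of each localized density is discretized into curves that are
    concatenated into a single shape vector. Also provides the traditional
    descriptors circularity, aspect ratio, and solidity; a PCA morphospace
    with descriptor correlations; linear-discriminant family classification
    with leave-one-out cross-validation and a label-permutation null;
    family-level shape-diversity estimates from per-component variance ranks;
    and a parametric generator of synthetic leaf outlines (simple, lobed,
    serrated, compound) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    polyclip,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
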