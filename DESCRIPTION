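Package: fractalpp
Title: Fractal Analysis and Unsupervised Clustering of Planar Point Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes spatial point patterns through local growth curves
    (per-point neighbor counts over a grid of radii), global and local fractal
    dimensions (box counting and sandbox counting with log-log slope fits), the
    multipoint Morisita index with its intrinsic-dimension estimator and
    Morisita-based redundancy reduction, and a validated unsupervised-learning
    pipeline: clusterability (Hopkins statistic), cluster-number voting over
    internal validity indices, k-means, PAM, CLARA, hierarchical clustering and
    self-organizing maps, plus per-cluster density and fractality profiles.
    Includes validity-domain geometry (polygons with holes), CSR-in-domain
    simulation and synthetic fixtures with known fractal dimension.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    cluster,
    mclust,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
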