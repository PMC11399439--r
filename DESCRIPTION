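Package: chainmatch
Title: Geometry-Informed Detection of Chain-Like Particle Assemblies in
    Multi-Color Super-Resolution Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Object-based colocalization analysis for multi-color
    super-resolution microscopy images in which the biological complex of
    interest is a chain of k differently labeled particles. Detects the
    maximal set of disjoint chains whose consecutive inter-particle
    distances stay below a colocalization threshold by solving an
    unbalanced multi-marginal optimal transport problem as an integer
    minimum-cost network flow, reports structure abundances and abundance
    curves over a threshold range, corrects abundances for incomplete
    per-channel labeling efficiencies with an unbiased multinomial
    estimator and asymptotic chi-squared confidence regions, and ships a
    STED-like image simulator plus a local-maxima spot detector to
    validate the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
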