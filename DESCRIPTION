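Package: afmtexture
Title: Surface Texture, Fractal and Minkowski Analysis of AFM Height Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the nanoscale texture of atomic force
    microscopy (AFM) height maps, motivated by studies of nanodrug
    aggregation on biological surfaces. Provides amplitude roughness
    statistics and the height probability distribution, six fractal
    dimension estimators (cube counting, triangulation, variance, power
    spectrum, structure function, variation) fitted on log-log scaling
    curves, threshold-sweep two-dimensional Minkowski functionals (volume,
    boundary, Euler-Poincare connectivity), and morphological tip
    dilation/erosion to compensate tip-surface convolution. A synthetic
    surface generator (self-affine fractional Brownian backgrounds with
    deposited particle fields and exact geometric fixtures) supplies ground
    truth for validation, and a pipeline assembles per-sample reports and
    cross-sample comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
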