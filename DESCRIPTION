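Package: pavetopo
Title: Topology of Pavement-Cell Tissues: Division Rules, Neighbour
    Statistics and Label-Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the neighbourhood topology of planar
    epithelial tissues such as the Arabidopsis leaf pavement-cell layer.
    Provides a graph-based cell-division simulator on a rotation-system
    (cyclically embedded) tissue graph with Equal, Random and Pascal
    (binomial) neighbour-split rules under with- and without-replacement
    division scheduling; neighbour-number distributions with moments and
    the Lemaitre-type alpha statistic; analytic and empirical division
    matrices; Aboav-Weaire and Lewis curves and normalised-area
    regressions; a region-adjacency topology extractor for segmented
    label images (TIFF/PNG) with boundary-validity tiers and shape
    descriptors; lineage-tracking division-event detection; and seeded
    synthetic-data generators (Voronoi label frames, two-frame division
    time-lapses, rule event streams) so the whole pipeline is testable
    without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
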