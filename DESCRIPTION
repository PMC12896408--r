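Package: ifcClusters
Title: Detection and Characterisation of Circulating Tumour Cell
    Clusters from Imaging Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated, testable pipeline for detecting and
    characterising circulating tumour cell (CTC) clusters in
    neuroblastoma blood samples analysed by imaging flow cytometry.
    Generates synthetic multi-channel event images (brightfield, GD2,
    CD45, DAPI) with known ground truth; gates events on object area to
    find candidates larger than a single cell and ranks them by GD2
    expression; segments nuclei, calibrates marker-positivity thresholds
    from negative controls and applies GD2/CD45/DAPI marker logic to type
    cells; calls clusters from contact graphs of intact nucleated cells
    and labels them homotypic or heterotypic; and aggregates per-sample
    counts into cohort summaries with per-mL normalisation, Spearman rank
    correlation, Fisher's exact and chi-square tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
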