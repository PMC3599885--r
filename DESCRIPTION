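Package: hicdyn
Title: Differential Chromatin Interaction Analysis from Binned Hi-C Contact Maps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of condition-dependent chromatin interaction
    changes from Hi-C read pairs: fixed-width genome binning, contact-matrix
    construction with duplicate removal, observed/expected Z-score
    normalization, per-region interaction frequency with hot/cold region
    calling, a bounded relative-ratio statistic that classifies gain and loss
    of intra- and inter-chromosomal contacts between two conditions, and
    integration of the resulting calls with epigenomic read tracks,
    transcription-factor binding peaks, rearrangement break-points and gene
    expression. A synthetic-data generator reproduces the statistical
    structure of a two-condition Hi-C study so that every stage of the
    pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
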