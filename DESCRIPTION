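Package: tastools
Title: Processing of TAS-Seq Single-Cell Read-Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing nanowell/bead single-cell RNA-seq data
    generated with terminator-assisted solid-phase cDNA amplification and
    sequencing (TAS-Seq): error-correcting parsing of multi-section bead
    barcodes, non-UMI gene-by-barcode counting, barcode-rank (knee plot)
    cell calling at the inflection point, distribution-based error
    correction (DBEC) of per-gene counts via biexponential transformation
    and equal-variance Gaussian mixture modelling, hashtag demultiplexing,
    and the quality-control, normalization, highly-variable-gene and
    cross-platform comparison statistics used to benchmark such data.
    Includes seeded synthetic-data generators with ground-truth manifests
    for validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
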