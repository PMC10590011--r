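Package: hotzones
Title: Identification of Transcription Factor High Accumulation (HOT) DNA Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects DNA zones with dense accumulation of transcription
    factor (TF) bindings from ChIP-seq-derived binding regions. Computes
    exact per-base accumulation tracks under three quantification
    strategies (distinct TFs, binding regions, or region bases intersecting
    a symmetric moving window of semi-width w), identifies dense zones with
    either a binding-region merging method or an overlap (constant-run)
    method, and selects high occupancy target (HOT) zones with data-driven
    thresholds (top-k-percentage or mean plus k standard deviations).
    Includes a synthetic-data generator, a brute-force per-base oracle for
    validation, annotation-overlap and cross-sample conservation summaries,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
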