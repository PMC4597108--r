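Package: cooccupy
Title: Composite-Site and Co-Occupancy Analysis of ChIP-Seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of transcription-factor co-occupancy on regulatory
    regions from ChIP-seq peak sets: position weight matrix scanning with
    exact p-value thresholds, classification of peak-summit windows by
    motif occurrence, detection of overlapping (composite) binding sites,
    permutation-based peak-set overlap enrichment against a random-placement
    null, two-nearest-gene target assignment, and intersection of bound
    genes with differential-expression calls to identify direct targets.
    Includes a ZOOPS expectation-maximisation motif discovery routine and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
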