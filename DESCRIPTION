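Package: t2ctools
Title: Targeted Chromatin Conformation Capture (T2C) Contact Maps, Domains
    and Enhancer Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds restriction-fragment-resolution proximity (contact)
    matrices for a capture region from positioned ligation read pairs, as
    produced by targeted chromatin capture (T2C) experiments. Provides
    in-silico restriction digestion with IUPAC-ambiguous recognition sites,
    fragment-level matrix construction with configurable pair filtering,
    binning to a chosen resolution, insulation-score TAD boundary detection,
    observed/expected loop calling, enhancer-candidate calling from H3K27ac
    peaks with conservation support inside distal loop anchors, and
    position-weight-matrix motif scanning at a relative-score threshold.
    A synthetic-data module generates capture regions and ligation pairs
    with planted TAD, loop, enhancer and motif structure so that every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    jsonlite,
    graphics,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
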