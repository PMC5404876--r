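Package: rrfscan
Title: Discovery and Profiling of rRNA-Derived Small RNA Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for rRNA-derived small RNA fragments (rRFs)
    in small RNA sequencing data. Cleans and collapses sRNA-seq reads,
    aligns them to an annotated rDNA reference allowing at most one
    mismatch or one 1-nt gap, classifies fragments by their termini
    relative to mature rRNA gene boundaries (rRF5, rRF3, body), detects
    terminus-anchored series whose lengths vary in 1-bp steps, and tests
    terminal enrichment against a uniform-degradation null. Includes a
    synthetic-library generator with ground truth for end-to-end
    validation without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
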