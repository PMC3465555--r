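Package: regulonscreen
Title: Integrative ChIP-seq and Transcriptome Screening for Direct
    Transcription-Factor Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying candidate direct targets of a
    transcriptional repressor by intersecting genome localization
    (ChIP-seq peak) data with differential-expression studies. Implements
    TSS-window and flanking-sequence peak-to-gene assignment, top-N peak
    normalization across factors, multi-factor binary occupancy matrices
    with Pearson-correlation hierarchical clustering, region- and
    gene-level Venn intersections, upper-tail hypergeometric enrichment
    of bound genes among derepressed genes, and a fully deterministic
    synthetic-data generator with planted co-binding structure and
    planted responder genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
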