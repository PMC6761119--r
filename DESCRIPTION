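Package: ffloop
Title: Discovery of miRNA-TF-Target Coherent Type-2 Feed-Forward Loops
    from Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens promoter-level (CAGE) and small-RNA time-course
    expression data for coherent type-2 feed-forward loops in which a
    microRNA represses both a transcription factor and one of that
    factor's activated target genes. Combines expression, fold-change and
    anti-correlation filters with canonical TargetScan-style seed-site
    prediction on 3'UTRs and ChIP-seq peak-to-TSS evidence for the
    TF-target edge, and provides a partial-correlation stage relating
    gene expression to clinical phenotypes by multiple regression. A
    synthetic-data generator with planted ground-truth loops and
    per-filter decoy genes makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
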