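Package: commitpoint
Title: Timing Regulatory-Element Establishment Along Hematopoietic Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates BED-format peak sets from chromatin accessibility
    (ATAC-seq), histone-mark ChIP-seq (H3K27ac, H3K4me1) and DNA-methylation
    enrichment (MBD-seq) with TPM expression tables to time the establishment
    of active regulatory elements (AREs) along ordered hematopoietic lineages.
    Provides replicate- and ensemble-consensus peak calling, ARE derivation by
    H3K27ac/ATAC intersection, cell-specificity partitioning, earliest-stage
    establishment inference, poised/active/open enhancer classification
    against progenitor reference marks, nearest-TSS promoter/enhancer distance
    classes, transcript-maintenance accounting with proportion tests,
    methylation-overlap fractions, and a region-randomization permutation test
    for overlap enrichment. A synthetic-cohort generator with planted ground
    truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
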