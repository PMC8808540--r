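Package: chipscape
Title: Comparative Analysis of Cell-Type-Resolved Histone-Modification ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for comparing histone-modification
    ChIP-seq landscapes (H3K27ac, H3K4me3) across sorted cell populations
    and donor conditions. Provides input-subtracted depth-normalized signal
    tracks on fixed genome windows, fraction-of-reads-in-peaks and
    peak-count quality control, a Poisson local-background peak caller,
    majority-rules consensus and master peak sets, a negative-binomial Wald
    test for differential histone modification, summit-anchored enhancer
    calling with promoter exclusion, position-weight-matrix motif
    enrichment with cell-type-specificity logic, GWAS-SNP proximity
    annotation, and a seeded synthetic-study generator with planted ground
    truth for validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
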