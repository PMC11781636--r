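Package: methylrad
Title: Site-Level DNA Methylation Profiling from Methylation-Dependent
    Restriction Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for MethylRAD-style reduced-representation
    DNA methylation profiling, in which a methylation-dependent restriction
    enzyme (FspEI) releases short tags at methylated CCGG and CCWGG sites
    and tag depth proxies site methylation. Provides electronic digestion
    of a reference genome into a stranded site catalog, read quality
    control with a raw-to-clean accounting ladder, unique tag-to-site
    matching with reads-per-million normalization, a negative-binomial
    exact-style two-group differential test with median-of-ratios size
    factors, genomic feature and metagene annotation, promoter
    methylation versus expression correlation with four-quadrant
    classification, hypergeometric gene-set enrichment, and a fully
    seeded synthetic-data generator so every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
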