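Package: homoeocomp
Title: Homoeolog Transcriptional Compensation Analysis in Polyploid Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects active transcriptional compensation between wheat
    homoeologs from TILLING point-mutation data and RNA-seq counts.
    Provides consequence calling for EMS-induced single-nucleotide
    variants against GFF3 gene models, the variant filtering cascade
    (premature termination codon or synonymous, homozygous in the mutant
    line but absent from wild type, member of a homoeolog group), a
    self-contained negative-binomial Wald differential-expression test
    with median-of-ratios normalization and Benjamini-Hochberg FDR,
    per-group compensation calls (upregulation of a non-mutated
    homoeolog), chi-squared comparison of PTC versus synonymous mutation
    classes, Euclidean-distance homoeolog expression-bias categories for
    triads and dyads, Pfaffl-ratio RT-qPCR analysis, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
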