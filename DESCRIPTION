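Package: paeomics
Title: Downstream Multi-Omic RNA-Seq Analysis of Pulmonary Artery Embolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the downstream transcriptomic
    pipeline used to profile porcine pulmonary arteries affected by embolism
    (PA-E) against controls (CTR): negative-binomial differential expression
    with median-of-ratios normalisation and Wald testing, long non-coding RNA
    identification by a three-scorer coding-potential consensus with
    trans-correlation networking, percent-spliced-in (PSI) differential
    alternative splicing over the five canonical event geometries, the
    delta-AAF allele-specific-expression cascade with region-mask filtration
    and variant consequence annotation, Fisher/Benjamini-Hochberg functional
    enrichment, and Pfaffl-method qPCR validation. A synthetic-data module
    generates genomes, gene models, counts, junction reads, allele counts and
    Cq tables with planted truth so every stage has a recovery oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
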