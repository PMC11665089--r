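Package: methtile
Title: Windowed Whole-Genome Bisulfite Methylome Analysis and DMR Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for stage-wise analysis of whole-genome bisulfite
    sequencing (WGBS) methylomes in plants. Aggregates per-cytosine
    methylation counts from Bismark-style cytosine reports into fixed
    50 bp windows per sequence context (CG, CHG, CHH) with qualification
    filters, calls differentially methylated regions (DMRs) between
    sample groups using a pooled exact count test, Benjamini-Hochberg
    adjustment and a genome-wide effect-size gate, classifies windows by
    genomic feature (gene, gene & TE, TE, intergenic), stratifies
    transposable elements by length, profiles DMR positions along
    chromosomes with pericentromere enrichment, and computes meta-feature
    methylation profiles across scaled gene and TE bodies with flanking
    regions. A beta-binomial synthetic methylome generator with truth
    tables makes every stage of the pipeline testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
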