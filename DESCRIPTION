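Package: rrbsdmf
Title: Fragment-Based Differential Methylation Analysis for RRBS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fragment-level analysis of reduced representation bisulfite
    sequencing (RRBS) methylomes, using in-silico MspI fragments as the unit
    of analysis. Provides in-silico digestion with size selection, ingestion
    of Bismark-coverage-style per-CpG counts with strand merging, pooled
    fragment methylation levels with coverage filtering, differential
    methylation calling by two-sided Fisher exact tests with Bonferroni
    correction and an effect-size threshold, cross-pair common-fragment
    intersection with direction concordance, genomic-context annotation
    (promoter/exon/intron/junction/intergenic and CpG-island
    core/shore/shelf/open sea), hypergeometric gene-set enrichment, global
    methylome summaries, and a seeded simulator of paired tumour-tissue and
    cell-line count data with planted differentially methylated fragments
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
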