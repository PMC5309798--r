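Package: dosagescope
Title: Dosage-Sensitivity Analysis of Copy Number Variant Pathogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the relationship between gene dosage
    sensitivity and the clinical interpretation of human copy number
    variants (CNVs). Merges benign and pathogenic CNV calls into CNV
    regions (CNVRs), computes per-base CNV coverage and detects
    local-maximum "peak" subregions that proxy recurrently affected
    critical regions; classifies protein-coding genes by their pattern
    of benign/pathogenic gain/loss CNV overlap; scores the copy-number
    conservation of each gene across 13 mammalian genomes from
    orthology annotations; provides a length- and
    chromosome-preserving CNV location-randomization null with
    permutation summaries; and implements the enrichment battery
    (chi-squared tests with adjusted residuals, Mann-Whitney U,
    Fligner-Killeen, hypergeometric term enrichment with a custom
    background and Bonferroni correction). A synthetic-data generator
    emulates the dbVar/Ensembl-style inputs so the full pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
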