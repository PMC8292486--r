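Package: sgegwas
Title: Social Genetic Effects, Deregressed Breeding Values and
    Haplotype-Based GWAS for Group-Housed Livestock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-layer genetic analysis of socially affected traits in
    group-housed animals. Layer one fits a social (indirect) genetic
    effects mixed model by average-information REML, extracts direct and
    social breeding values with prediction-error variances, and deregresses
    them into pseudo-phenotypes. Layer two runs single-locus and
    haplotype-based mixed-model association scans on the deregressed
    breeding values with a genomic relationship matrix, Bonferroni
    thresholds, genomic-control diagnostics, Gabriel-style haplotype-block
    detection, multi-allelic haplotype coding, and QTL-region reporting.
    A seeded synthetic-cohort generator (LD-blocked phased genotypes, pen
    and litter structure, feeder visit records) makes every stage testable
    without animal data. Includes readers and writers for PLINK binary and
    phased VCF genotypes and the standard chip quality-control filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
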