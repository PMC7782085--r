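Package: ampliconcord
Title: Paired-Biopsy Concordance Analysis for Amplicon Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-usable pipeline for amplicon-panel targeted sequencing of
    paired tumour specimens (core needle biopsy versus fine-needle aspiration):
    read-pair to amplicon assignment with primer trimming, count-based copy-number
    calling by median normalization and exact least-squares segmentation of ordered
    log2 ratios, somatic variant filtering at explicit depth/allele-fraction
    thresholds, rule-based pathogenicity validation including tumour-suppressor
    bi-allelic inactivation logic, and per-patient concordance statistics
    (arcsine-square-root Pearson correlation of allele fractions, per-pair segment
    correlation with Benjamini-Hochberg control, Mann-Whitney and Kruskal-Wallis/Dunn
    group comparisons). Ships a seeded synthetic paired-cohort generator with known
    truth (shared somatic events, sample-type-dependent tumour cellularity) so the
    whole pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
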