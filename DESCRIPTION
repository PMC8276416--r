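Package: ccotim
Title: Immuno-Genomic Classification of Colorectal Cancer Organoid Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for immuno-genomic classification of paired colorectal
    cancer organoid (CCO) / primary-tumor cohorts: bespoke variant rules
    (biallelic calling by variant allele fraction, TP53 gain-of-function
    lookup, five-locus microsatellite-instability classification), copy-number
    fraction and fusion-candidate filtering, gene-set signature scoring with
    HLA class II selection and quantile stratification, k-means based
    intrinsic subgrouping and Ca-IIP (cancer-intrinsic immunogenic
    properties) calling, template-based tumor immune microenvironment (TIM)
    classification, a sample-level Kolmogorov-Smirnov enrichment statistic
    with permutation null, and survival association (Kaplan-Meier, log-rank,
    Cox). Includes a synthetic paired-cohort generator so the full pipeline
    is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
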