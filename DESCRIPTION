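Package: poolcoev
Title: Pooled-Population Genomics for Experimentally Evolved Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of whole-genome pooled sequencing (pool-seq) of
    experimentally evolved bacterial populations founded from a mixture of
    known strains. Estimates per-strain abundance from substitution
    frequencies at strain-diagnostic sites using a robust mode estimator,
    applies post-calling variant filters (coverage quantiles, Fisher
    strand-bias, indel collisions, minor allele frequency), detects copy
    number variation from the across-sample variance of coverage ranks,
    calls horizontally transferred fragments from competitively assigned
    reads, computes coverage-adjusted Watterson's theta, Tajima's pi and
    Tajima's D in sliding windows, and relates genomic features to
    phenotypes via weighted regression and nested ANOVA with
    Benjamini-Hochberg correction. A synthetic-data generator provides
    pooled samples with known truth so every stage has parameter-recovery
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings,
    Rsamtools,
    vcfR,
    withr
Config/testthat/edition: 3
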