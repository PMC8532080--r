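Package: xlburden
Title: X-Linked Rare-Variant Burden Testing with Firth Logistic Regression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-based collapsing burden analysis for X-chromosome rare
    variants in male case/control cohorts. Provides genotype- and site-level
    quality filters (depth, genotype quality, minor read ratio, reference
    call rate, decoy regions, multi-allelic sites, cohort missingness, span),
    qualifying-variant selection by population minor allele frequency and
    consequence class, per-gene carrier collapsing, in-cohort ancestry
    principal components, a Firth bias-corrected logistic likelihood-ratio
    test with covariate adjustment, Bonferroni correction over eligible
    genes, reporter-activity loss-of-function allele classification,
    cumulative hemizygous allele-frequency summaries, and a synthetic-cohort
    generator for end-to-end validation without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
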