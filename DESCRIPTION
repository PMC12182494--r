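Package: microMR
Title: Two-Sample Mendelian Randomization for Microbiome Exposures
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for two-sample Mendelian randomization of
    GWAS summary statistics, motivated by analyses of gut-microbiota taxa
    on childhood neuroblastoma risk. Provides instrument selection
    (p-value threshold filtering and greedy LD clumping), allele
    harmonization between exposure and outcome samples (allele-order
    swaps, strand flips, palindromic variants), four causal estimators
    built from per-variant Wald ratios (inverse-variance weighted,
    MR-Egger, weighted median, weighted mode), heterogeneity and
    leave-one-out sensitivity analyses, interval-based SNP-to-gene
    annotation, and a seeded synthetic GWAS generator with known ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: StatisticalMethod, GenomeWideAssociation, SNP, Microbiome
RoxygenNote: 7.3.3
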