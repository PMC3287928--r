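Package: synthcorr
Title: Rare-Variant Burden Prediction of Common-Variant Genotypes in
    Unrelated and Family Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how often simple rare-variant burden scores predict
    the genotypes of common variants in the same gene, the genomic
    precondition for synthetic association.  Provides a structured-population
    genotype simulator with pedigree gene dropping, minor-allele-frequency
    classification and gene selection filters, recursive pedigree kinship,
    ordinary least-squares and kinship variance-component regressions of
    common-variant genotype scores (CVGS) on summed rare-variant genotype
    scores (SRVGS) with optional principal-component stratification
    covariates, within-gene linkage-disequilibrium summaries, and an
    end-to-end pipeline producing cross-classified nominal-significance
    tables for unrelated and family cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
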