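Package: crosspop
Title: Trans-Ethnic Transferability of GWAS Index SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate whether genome-wide significant index SNPs
    discovered in one ancestral population replicate in another, using only
    GWAS summary statistics and small reference genotype panels. Implements
    summary-statistics harmonization and quality control, greedy P-value
    clumping for index-SNP selection, winner's-curse correction of discovery
    effect sizes under significance truncation, sample-size standardization
    of target-population standard errors, the trans-ethnic false discovery
    rate (transFDR) classifier based on an empirical-Bayes local false
    discovery rate two-group model, per-SNP effect-heterogeneity tests with
    a disattenuated cross-population effect correlation, cross-population
    heritability and genetic-correlation hypothesis tests, and
    reference-panel population-genetic metrics (LD scores, Hudson's Fst,
    cross-population coefficients of variation). A synthetic-data module
    generates paired summary statistics and LD-block genotype panels with
    known truth for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
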