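Package: xciskew
Title: X-Chromosome Inactivation Skew from XIST Allele-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies skew of X-chromosome inactivation (XCI) in female
    samples from allele-specific expression of XIST at phased heterozygous
    SNPs, classifies samples as skewed or random, and runs the downstream
    cohort analyses: tissue prevalence and concordance of skew, age
    association (regression, lowess inflection, stratified tests),
    discordant monozygotic-twin tests, smoking association, and
    age-stratified ACE twin variance decomposition by maximum likelihood
    with Falconer cross-checks and double-entry intraclass Spearman
    correlations. A synthetic twin-cohort generator with known latent skew,
    ACE covariance structure and beta-binomial read sampling makes every
    stage testable without access-controlled data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
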