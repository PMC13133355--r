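Package: carriermr
Title: Two-Sample Mendelian Randomization for Reproductive Traits and Breast
    Cancer Risk in Pathogenic Variant Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) linking
    genetically predicted age at natural menopause and age at menarche to
    breast cancer risk, with emphasis on ascertained BRCA1/BRCA2 carrier
    cohorts. Provides GWAS summary-statistic harmonization (allele alignment,
    palindromic-variant exclusion), polygenic score construction with the
    theoretical per-SD trait effect under Hardy-Weinberg equilibrium,
    instrument validation in family-based cohorts via right-censored (Tobit)
    weighted linear regression with family-clustered sandwich variance and
    weighted-cohort ascertainment correction, the standard univariable MR
    estimator suite (inverse-variance weighted, MR-Egger, simple/weighted/
    penalized-weighted median, radial outlier removal, heterogeneity
    statistics) plus a horseshoe-prior Bayesian pleiotropy-robust estimator,
    and multivariable MR with total/direct/mediated effect decomposition.
    Includes seeded synthetic-data generators for summary statistics under
    configurable pleiotropy and for ascertained carrier cohorts with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    rjags
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    survival,
    jsonlite
Config/testthat/edition: 3
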