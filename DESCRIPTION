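Package: proxyval
Title: Validating Proxy Lipid Phenotypes with Agreement Statistics and
    Genomic Variance Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for validating an indirect (proxy) phenotype against a
    reference measurement in aquaculture breeding populations. Implements
    family-structured simulation of SNP genotypes and two-method lipid
    phenotypes, SNP quality control and the VanRaden method-1 genomic
    relationship matrix, phenotypic agreement statistics (Lin's concordance
    correlation coefficient, coefficient of variation, root mean square error
    of prediction, paired tests), and average-information REML estimation of
    variance components under univariate, repeatability and bivariate animal
    models with delta-method standard errors for heritability, repeatability
    and genetic correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
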