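Package: mlrgwas
Title: Mixed Logistic Regression for Genome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast association testing and effect estimation for binary traits
    under the mixed logistic regression model. Fits the null model once by
    penalized quasi-likelihood (PQL) with AI-REML variance-component updates,
    then tests each variant with either the approximate maximum likelihood
    estimator (AMLE, whose Wald test coincides with the GMMAT score test) in
    O(n^2) per SNP, or the Offset two-step estimator in O(n) per SNP. Includes
    comparison baselines (plain logistic regression, linear mixed model score
    test), genomic-relationship-matrix and principal-component utilities,
    stratified quantile-quantile diagnostics for heterogeneous-prevalence
    cohorts, and a seedable simulator of spatially structured cohorts with
    cryptic relatedness for type-I-error, power and bias experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
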