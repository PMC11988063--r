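Package: smallgp
Title: Genomic Prediction of Test-Day Milk Traits in Smallholder Dairy Herds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for genomic prediction of test-day milk fat
    percentage in crossbred smallholder dairy cattle. Provides sequential
    phenotypic and genotypic quality control with audit ledgers, a stage-1
    repeatability animal model (EM-REML and Henderson's mixed-model equations)
    that produces adjusted test-day records, the VanRaden genomic relationship
    matrix, and stage-2 Bayesian inference by Gibbs sampling: a random
    regression GBLUP sampler with Legendre polynomial covariates and a
    BayesR-style four-component mixture sampler for SNP effects. Outputs
    variance components, heritability, and genomic-estimated breeding values
    (GEBV). A synthetic-data module emulates the smallholder herd structure
    (mostly one- and two-cow herds) so every stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
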