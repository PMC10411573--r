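Package: diffgblup
Title: Difference-Response GBLUP for Predicting Tested Lines in Untested
    Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction of tested lines in untested environments
    from balanced multi-environment trials. Implements conventional GBLUP
    predictors with and without genotype-by-environment interaction
    (VanRaden genomic relationship matrix, incidence-based environmental
    kernel, Hadamard interaction kernel) and a difference-response method
    that trains on pairwise between-environment phenotype differences and
    reconstructs target-environment predictions as an ensemble. Includes a
    restricted maximum likelihood (REML) mixed-model engine with an
    optional Gibbs sampler, leave-one-environment-out cross-validation,
    accuracy metrics (average Pearson correlation, Best10/Best20 top-line
    capture, normalized RMSE, relative gains), a multi-environment trial
    simulator with controllable environment-mean shifts, and readers and
    writers for genotype and phenotype tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
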