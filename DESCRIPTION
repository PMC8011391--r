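Package: specurate
Title: Species Misclassification Detection and Correction for Genotyped
    Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects and corrects species misclassifications in genotyped
    plant genetic-resources collections. Provides five classifiers
    (1-nearest neighbour, a conservative 3-nearest-neighbours rule with
    explicit ambiguity, neighbour-joining smallest-subtree classification,
    random-forest out-of-bag voting, and categorical naive Bayes), a
    random-forest proximity outlier screen, genotype import and filtering
    from VCF or delimited dosage/dominant matrices, a
    misclassification-injection benchmark over species representation and
    error-rate grids, and classifier comparison by Friedman Aligned Ranks
    with Finner correction. Includes a Balding-Nichols style synthetic
    multi-species genotype generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    randomForest,
    ranger,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
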