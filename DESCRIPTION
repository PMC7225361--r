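Package: grsgxe
Title: Genetic Risk Score Tests for Gene-Environment Interaction at Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage genetic risk score (GRS) tests of gene-environment
    interaction at a candidate gene. Stage one estimates per-SNP weights from
    covariate-adjusted phenotypes by ridge, lasso, or elastic-net regression
    with the penalty chosen by 10-fold cross-validation; stage two tests
    whether an environmental exposure modifies the effect of the standardized
    GRS, yielding a p-value together with a direction of interaction
    (exacerbation or attenuation). Includes three competing set-based
    interaction tests (a sign-score test with marginal filtering, a
    variance-component score test, and an adaptive combination of per-SNP
    interaction Bayes factors with sequential resampling), an LD-structured
    genotype simulator, phenotype simulators for continuous and binary traits,
    and a simulation framework for type-I error, power, sign-misspecification,
    and filtering sensitivity/precision studies. PLINK 1 binary genotype files
    are read and written natively, with call-rate, exact Hardy-Weinberg, and
    minor-allele-frequency quality-control filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
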