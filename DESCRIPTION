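Package: finemapr
Title: Regional Fine Mapping of Case-Control Association Signals with
    Sparse Penalized Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine mapping a genomic region in a case-control
    study: single-SNP and conditional dosage logistic scans with a
    stratification covariate, post-imputation SNP quality control (exact
    Hardy-Weinberg test, INFO scores, retention typing), stochastic model
    search under a normal-exponential-gamma (NEG) sparsity penalty,
    lasso/elastic-net comparison fits with LD pruning, collapsing of
    selected models into linkage-disequilibrium equivalence classes with
    unpenalized refits, and variance-explained accounting. Includes a
    synthetic case-control genotype simulator (haplotype-mosaic LD,
    Balding-Nichols stratification, additive logistic risk, imputation
    noise calibrated to a target INFO score) so the whole pipeline is
    testable without access-controlled data, plus readers and writers for
    Oxford GEN/SAMPLE and VCF dosage formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    glmnet,
    knitr,
    readr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
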