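Package: gvburden
Title: Gene-Wise Variant Burden Scoring and Multigene Prediction of
    Thiopurine Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pharmacogenomic analysis pipeline for thiopurine (6-mercaptopurine)
    dose-intensity phenotypes in pediatric acute lymphoblastic leukemia.
    Implements gene-wise variant burden (GVB) scoring -- the geometric mean of
    SIFT scores of carried coding variants, with recessive masking for
    designated common variants -- single- and multigene composition, consequence
    and deleteriousness (SIFT/CADD) variant filtering, covariate-adjusted
    genetic-model association testing with a discovery/replication screen,
    star-allele metabolizer phenotyping for NUDT15 and TPMT, and systematic
    classifier evaluation (confusion-matrix metrics, ROC/AUC with bootstrap
    confidence intervals, Youden-optimal cutoffs). Ships a synthetic-cohort
    generator that reproduces the statistical structure of the target study
    design so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
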