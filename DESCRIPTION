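Package: ponvrisk
Title: Pharmacogenetic Risk Analysis of Postoperative Nausea and Vomiting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for pharmacogenetic association studies of
    postoperative nausea and vomiting (PONV): genotype quality control with
    Hardy-Weinberg testing, CYP star-allele diplotype assignment and activity
    scoring (including CYP2D6 copy number and CYP1A2 smoking induction),
    covariate-adjusted logistic genetic association fitted by iteratively
    reweighted least squares, EM haplotype frequency estimation with pairwise
    linkage disequilibrium and block detection, and genotype-adjusted Apfel
    risk scoring evaluated by sensitivity, specificity, number needed to
    genotype, and ROC/AUC. A calibrated synthetic cohort generator emulates
    the covariate prevalences, allele frequencies, LD structure, and outcome
    model of a surgical PONV cohort so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
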