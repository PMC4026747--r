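Package: tlpassoc
Title: Penalized Regression and Global Tests for Quantitative-Trait Rare-Variant Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association testing between a quantitative trait and a group of
    rare variants. Provides seven global tests built on ordinary-least-squares
    score statistics (F, Score, SSU, SSUw, UminP, Sum, adaptive Sum) with
    asymptotic or permutation p-values, and four penalized-regression tests
    (Lasso, graph-fused Lasso, and truncated-L1-penalty variants TLP-S and
    TLP-SG) whose p-values are calibrated by permutation with per-permutation
    AIC tuning of the penalty parameters. Includes a latent-Gaussian haplotype
    simulator for rare and common variants and replicate-level harnesses for
    power, variable-selection and estimation studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    mvtnorm,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
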