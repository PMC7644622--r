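Package: neurocca
Title: Permutation-Calibrated Canonical Correlation Analysis of Genetic
    Risk and Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of psychiatric-risk SNP dosages and structural
    brain connectomes. Discovers modes of genome-connectome covariation with
    canonical correlation analysis on PCA-reduced blocks, calibrates mode
    significance with a max-statistic permutation test, and computes
    per-feature canonical strengths with permutation p-values and grouped
    Benjamini-Hochberg FDR control. Downstream analyses cover
    clumping-and-thresholding polygenic risk scores with permutation
    correction over the threshold grid, behavior correlations combined by a
    permutation-based Fisher test for dependent p-values, single-mediator
    mediation of genetic risk through the connectomic score, and a
    robustness battery (split-half, principal-component sensitivity, SNP
    subsets, subject exclusion, hubs). A synthetic-data generator plants a
    joint latent mode of known canonical correlation so the whole pipeline
    is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
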