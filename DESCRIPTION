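Package: methpattern
Title: DNA Methylation Pattern Discovery by Fuzzy NMF Biclustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subgroups DNA methylation array cohorts (beta-value matrices) by
    variable-CpG selection, k-means feature reduction, fuzzy non-negative
    matrix factorization biclustering with consensus and permutation
    significance filtering, k-means derivation of CpG modules and sample
    methylation patterns, UMAP embedding and projection of external cohorts,
    and downstream cohort statistics (pairwise Wilcoxon tests with Bonferroni
    correction, Fisher enrichment odds ratios, epiCMIT mitotic-clock scores).
    Includes a synthetic-cohort generator with planted module-by-pattern
    structure, tumor-cell-content dilution toward a bystander profile, and
    beta-distributed noise, so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils,
    uwot
Suggests:
    mclust,
    withr,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
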