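Package: metabnet
Title: Serum Metabolomics Case-Control Association and Network Pipeline
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for serum metabolomics case-control
    studies of dopaminergic movement disorders (Parkinson's disease and restless
    legs syndrome against population controls). Implements run-day median
    normalization, missingness filtering, chained-equations imputation,
    metabolome-wide association scans with Bonferroni control and shared/unique
    set logic, all-pairs metabolite-ratio scans with the p-gain statistic,
    shrinkage-based Gaussian graphical model inference with a dual-significance
    edge rule, and a candidate-SNP metabogenomic scan. Ships a synthetic cohort
    generator with known ground truth (sparse precision structure, run-day
    batch effects, left-censored missingness, injected group and genotype
    effects) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
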