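Package: dmrbeta
Title: Differential Methylation Region Calling with Depth-Weighted Beta
    Regression and cis Methylation-Expression Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for targeted bisulfite sequencing
    studies with a two-factor (genotype by treatment) design. Clusters
    correlated adjacent CpG sites into methylation clusters, tests each
    cluster for group differences with a beta regression weighted on
    sequencing depth, controls the false discovery rate with
    Benjamini-Hochberg, subtracts baseline (vehicle-contrast) differences,
    blacklists genomic regions with an alternate strain background detected
    from an informative SNP panel, annotates calls by gene and CpG-island
    context, runs a simplified expression contrast stage (quantile
    normalization, log2, cell-means contrasts), and scans cis (+/- 1 Mb)
    cluster-probe pairs for methylation-expression association with
    genotype adjustment and exact binomial enrichment statistics. Includes
    a synthetic-data generator that emulates the assumed data structure
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    limma,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
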