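Package: mirsig
Title: Multi-Tissue MicroRNA Signature Discovery for Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering circulating microRNA
    signatures of metabolic disease from feature-by-sample microarray
    intensity matrices. Implements detection filtering against a fixed
    intensity threshold, U6 small-nuclear-RNA normalization anchored to the
    geometric mean, per-stratum Welch contrasts with signed (negative
    reciprocal) fold changes and a per-subject replication rule, multi-source
    Venn intersection and cross-species concordance selection, consensus
    miRNA-target voting across prediction databases, inverse miRNA-mRNA
    pairing, and 2^-ddCt relative quantification for qPCR validation.
    Includes a synthetic-data generator that plants a known eight-miRNA
    signature across five rat tissue sources and human blood cohorts so the
    whole pipeline can be exercised and benchmarked without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
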