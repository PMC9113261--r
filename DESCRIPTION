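Package: sigscore
Title: Tidy Single-Sample Gene Expression Signature Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified, tidy framework for computing single-sample gene
    expression signature scores from a normalized genes-by-samples matrix.
    Implements three generic single-sample enrichment engines (combined
    z-score, ssGSEA running-sum, and rank-based singscore), original-method
    archetypes (signature mean and coefficient-weighted sums), dedicated
    scorers for ESTIMATE-style tumor purity, CINSARC-style nearest-centroid
    risk classification, and Immunophenoscore-style weighted immune marker
    aggregation, together with a keyword-searchable signature registry, a
    gene-coverage checker, GMT import/export, deterministic synthetic cohort
    generators for validation, and a command-line interface. All scoring
    functions return a tibble with one row per sample and one column per
    signature.
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
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
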