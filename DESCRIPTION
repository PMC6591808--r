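Package: regulonmra
Title: Master-Regulator Analysis of Transcriptional Networks with Planted-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nominating master-regulator transcription factors from
    gene expression cohorts: mutual-information network inference with data
    processing inequality pruning, two-group differential-expression
    signatures, regulon enrichment (master regulator analysis) with
    attributable-fraction accounting, per-sample transcription factor
    activity profiling, regulon topology and synergy analysis, promoter
    motif-proximity network validation against a scrambled-motif null, and
    cross-cohort / cross-species conservation analysis. Includes a
    linear-Gaussian synthetic cohort generator with planted regulons and
    perturbed regulators so every stage can be benchmarked against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
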