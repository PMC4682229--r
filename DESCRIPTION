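Package: astronet
Title: Grade-Wise Differential Expression, Subtype Classification and
    Signature-Specific Regulatory Network Inference for Astrocytoma
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparative astrocytoma
    transcriptomics across WHO grades (pilocytic astrocytoma I,
    astrocytoma II/III, glioblastoma IV). Provides per-grade
    differential-expression state calling against normal brain
    references (Welch tests with FDR-adjusted q-values), exclusive
    Venn-style subset partitioning and category enrichment,
    centroid-correlation molecular subtype classification, set-logic
    derivation of the gene signature separating grade I from the
    higher grades, and sparse TF-to-target regulatory network
    inference via the lasso path with the covariance significance
    test. Includes a synthetic-cohort simulator with planted ground
    truth (grade-specific effects, a sparse TF coefficient matrix,
    subtype centroid mixtures and coupled mutation layers) for
    end-to-end recovery testing, plus hub/TF-hierarchy analysis,
    cross-cohort predictive validation and expression-versus-mutation
    integration.
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
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
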