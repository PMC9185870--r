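Package: virchip
Title: Predicting Cell-Type-Specific Chromatin Factor Binding from
    Transcriptome and Chromatin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised prediction of cell-type-specific chromatin factor
    binding in 200 bp genomic bins. Learns a bins-by-genes association matrix
    linking ChIP-seq binding signal to gene expression across training cell
    types, summarises it for a new cell type as a per-bin expression score,
    and combines that score with chromatin accessibility, genomic
    conservation, sequence motif scores and prior binding evidence in a
    multi-layer perceptron selected by leave-one-chromosome-out
    cross-validation on the Matthews correlation coefficient. Includes
    imbalance-aware evaluation (precision-recall with prevalence baseline),
    subsampling-based cluster-stability analysis, and a seeded synthetic
    cohort generator so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
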