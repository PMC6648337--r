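Package: refmap
Title: Frozen t-SNE Reference Maps for Heterogeneous Transcriptomics Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating gene expression data across studies and
    platforms around a frozen two-dimensional reference map. Provides
    normalized-mutual-information metrics (pNMI, eNMI, cNMI) that separate
    biological from technical (study-driven) clustering, variance-based
    feature selection with Barnes-Hut t-SNE embedding and Gaussian mean-shift
    clustering, a locked-embedding remapping optimizer that places new
    samples onto an existing map without disturbing it (Euclidean or
    correlation input distances for cross-platform data), gene-set-based
    correspondence between independently clustered datasets via single-sample
    enrichment scores with permutation null distributions and hypergeometric
    cluster enrichment, and reference-anchored (frozen quantile and fixed
    probe-effect median polish) normalization of new arrays. A synthetic
    multi-study data generator with planted phenotype modules and study batch
    effects supports end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    matrixStats,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
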