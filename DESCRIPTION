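Package: psnpredict
Title: Patient Classification with Patient Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds interpretable patient classifiers by integrating multi-modal
    clinical and 'omic data through patient similarity networks. Each feature
    (a pathway, a clinical variable, or a whole assay) becomes a weighted
    network over patients; features are scored by repeated regularized network
    integration on training subsamples, and held-out patients are classified by
    label propagation on the integrated network. Includes a sparse-genetic-variant
    workflow with binary pathway similarity and permutation-based label
    enrichment, network-based smoothing of somatic mutation profiles by random
    walk with restart, integrated-network aggregation with class-separation
    statistics, and a synthetic-data generator with planted class structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    Matrix,
    igraph,
    ggplot2,
    generics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
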