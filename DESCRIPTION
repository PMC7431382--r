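Package: miaglia
Title: Microglial Transcriptome Modules, Morphometry, and Fate Mapping for
    Maternal Immune Activation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for maternal immune activation (MIA)
    microglia studies. Discovers k-means expression modules on CPM-filtered
    microglial RNA-seq counts, scores cell-type purity from marker panels,
    runs a simplified gene-wise negative-binomial exact test, performs
    cross-species gene-module overlap enrichment on a one-to-one ortholog
    background with hypergeometric and permutation statistics, tests
    gene-network connectedness against permuted gene lists, scores dendritic
    spine subtypes and microglia-spine interactions in 3D on anisotropic
    voxel grids, computes microglial arbor morphometry (centrifugal branch
    order, Sholl profiles, convex hull volume), summarises BrdU/EdU
    fate-mapping demographics, and builds cross-modality Spearman
    correlation surfaces. A synthetic-data generator emulates the full study
    design so every stage is testable without raw data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    edgeR,
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
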