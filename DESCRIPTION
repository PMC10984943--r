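Package: ectcraft
Title: Spatial Niches and EcoCellTypes from Deconvolved Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of per-spot cell-type abundance estimates from
    deconvolved spatial transcriptomics (e.g. cell2location output on Visium
    sections). Builds pseudo-single-cell maps by discretizing abundances and
    jittering cells within spots; computes nearest-distance statistics between
    cell types and Shannon diversity; transfers pathologist annotation polygons
    to spots; identifies cross-patient spatial niches by isometric log-ratio
    transform of spot compositions, a batch-balanced k-nearest-neighbour graph
    and Leiden community detection; derives EcoCellTypes (groups of cell types
    co-occurring across niches) by hierarchical clustering of scaled niche
    compositions; and stratifies bulk-deconvolved cohorts by EcoCellType
    fractions with Kaplan-Meier, log-rank and Cox survival analysis. Includes a
    synthetic multi-section generator with known ground truth so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    survival,
    cluster,
    mclust
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
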