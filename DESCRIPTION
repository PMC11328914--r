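Package: mesotime
Title: Spatial Tumor-Immune Microenvironment Analysis for Multiplexed
    Immunofluorescence Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for per-cell segmentation tables exported from
    multiplexed immunofluorescence (mIF) tissue-microarray experiments:
    marker gating and cell phenotyping, per-core composition, density and
    coverage-adjusted (Chao-Shen) entropy profiling, Delaunay-graph
    cell-cell contact scoring with group comparison, cellular-neighborhood
    discovery by k-means on radius neighbor vectors with log-odds-ratio
    enrichment, and survival and marker association statistics. Includes a
    synthetic cohort generator with controlled composition, spatial
    clustering, intensity mixtures and survival outcomes for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deldir,
    FNN,
    RANN,
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
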