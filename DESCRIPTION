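Package: spatcorr
Title: Detection of Spatially Correlated Cell Sub-Populations in
    High-Content Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect spatially clustered sub-populations of
    responsive cells in per-cell feature tables exported from high-content
    imaging pipelines (CellProfiler-style CSV). Implements robust
    median/MAD feature normalization, PCA embedding with an
    explained-variance component rule, a resampling null distribution of
    pairwise Pearson correlations, k-nearest-neighbor median-correlation
    scoring with 95th-percentile classification, per-condition
    percent-correlated summaries, non-spatial marginal-distribution
    statistics, spatial map and bar-summary figures, and a seeded
    synthetic-data generator with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    graphics,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
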