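# spatcorr

Detection of spatially correlated cell sub-populations in high-content
imaging data.

## The problem

High-content imaging experiments quantify hundreds of morphology, intensity
and texture features for every segmented cell, along with each cell's
centroid inside its field of view (FOV). When a treatment acts on only a
sub-population of cells — and responding cells cluster in space, as
daughters of a common mother or through local paracrine signaling — the
response can be invisible in marginal feature distributions yet detectable
as excess feature-profile similarity between spatial neighbors. `spatcorr`
is for analysts of CellProfiler-style per-cell exports who want to detect
and quantify such spatially organized responder sub-populations.

## The statistic

For cells with normalized feature vectors $x_i \in \mathbb{R}^p$ and
Pearson correlation $r(x_i, x_j)$ across feature dimensions:

1. **Normalize** each feature against a reference population (one cell type
   at $t = 0$): $x \mapsto (x - \mathrm{median}) / (1.4826\,\mathrm{MAD})$,
   dropping features with $\mathrm{MAD} = 0$.
2. **Embed** with PCA, keeping the components that explain 99% of the
   variance; correlations are computed between PC score vectors.
3. **Null distribution**: per condition, draw 2000 random pairs of distinct
   cells (ignoring position) and record their correlations; the 95th
   percentile $q_{95}$ is the classification threshold.
4. **Score** each cell by the median correlation with its $k = 20$ nearest
   neighbors (Euclidean centroid distance, within the same FOV).
5. **Classify**: a cell is *spatially correlated* iff its median neighbor
   correlation exceeds $q_{95}$; summarize as percent-correlated per
   (cell type, treatment, time point).

A seeded synthetic-data generator produces multi-FOV tables with a
spatially clustered responder sub-population (Thomas-like cluster process,
mean-shifted features) and ground-truth labels, so sensitivity and
specificity of the whole pipeline are measurable.

## Worked example

Simulate a vehicle baseline and a treated condition in which 20% of cells
respond (a 2-SD shift on 30 of 300 features) in spatial clusters, then run
the full pipeline:

```r
library(spatcorr)

cfg <- default_config(
  seed = 1,
  simulate = list(
    params = list(n_fovs = 4),
    conditions = list(
      list(cell_type = "normal", treatment = "vehicle", time_point = 0,
           replicate = "r1", responder_fraction = 0),
      list(cell_type = "normal", treatment = "IGF-1", time_point = 1440,
           replicate = "r1")
    )
  )
)
res <- run_pipeline(cfg, "igf1_demo")
#> simulated 2000 cells over 2 condition(s)
#> cell type normal: 300 feature(s) retained, 0 dropped (MAD = 0)
#> cell type normal: 293 principal component(s) reach 99% of variance
#> 2000 cell(s) scored; 0 unscored
#> flagged fraction normal/IGF-1/t1440: 14.60%
#> flagged fraction normal/vehicle/t0: 0.00%
#> recovery vs ground truth: sensitivity 0.764, specificity 1.000

res$summary
#>   cell_type treatment time_point n_scored n_correlated percent_correlated
#> 1    normal     IGF-1       1440     1000          146               14.6
#> 2    normal   vehicle          0     1000            0                0.0

res$nulls[[1]]
#> null distribution of pairwise correlations
#>   condition: normal/IGF-1/1440/r1
#>   2000 draws from 1000 cells; q95 = 0.1276; median r = -0.0052
```

Reading the output: in the vehicle condition no cell's neighborhood is more
correlated than chance (0%), while in the treated condition 14.6% of cells
exceed the null threshold $q_{95} = 0.128$ — the planted 20% responder
sub-population, recovered at sensitivity 0.76 with no false positives
(cluster-edge responders, whose 20 nearest neighbors mix responders and
background cells, account for the shortfall; see the methods vignette).
The result directory contains every intermediate table (`cell_scores.csv`,
`percent_correlated.csv`, per-condition null draws), the Fig-style spatial
map and bar summary with their CSV twins, a `manifest.json` (config, hash,
seeds, filter counts) and a `log.txt` of every filtering decision.

Ingesting real CellProfiler exports instead of simulating: set
`cfg$input <- "cells.csv"` (column names remappable via `cfg$schema`), or
call `read_feature_table()` directly. A thin command-line driver lives at
`inst/cli/spatcorr.R` (`Rscript spatcorr.R run --config cfg.yaml --out dir`).

## Package layout

- `R/feature_table.R` — CellProfiler-style CSV ingest/round-trip
- `R/simulate.R` — synthetic generator with ground truth
- `R/normalize.R`, `R/pca.R` — robust normalization, PCA component rule
- `R/spatial.R` — null distribution, kNN scoring, classification, summaries
- `R/popstats.R` — area normalization, Kruskal–Wallis, percent change
- `R/plots.R` — spatial maps and bar summaries (with CSV twins)
- `R/pipeline.R` — config-driven end-to-end driver with manifest/logging
- `vignettes/spatial-correlation.Rmd` — methods, design choices, limitations
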