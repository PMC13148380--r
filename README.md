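# stainscape

Quantitative analysis of spatial staining patterns in brightfield
immunohistochemistry (IHC) images, together with the expression-level
readouts that typically accompany such studies: per-cell H-score / percent
positivity, a signed-sum gene-signature activity score, and
correlation-distance clustering of expression profiles. The package is
aimed at groups quantifying immune-cell (e.g. macrophage F4/80) spatial
patterning in tissue sections — dispersed versus aggregated staining,
recruitment to damaged regions — with matched bulk RNA-seq.

Every stage is driven by synthetic generators with planted ground truth
(histology images, per-cell intensity tables, expression matrices), so the
full pipeline is testable end-to-end without any external data.

## What it computes

**Tile-based GLCM texture pipeline.** A grayscale brightfield image is
normalized by the mean of a 200×200 background patch, a 1500×1500 region of
interest is tiled into an 8×8 grid (cut positions at rounded multiples of
187.5 px: 0, 188, 375, 563, 750, 938, 1125, 1313, 1500), tiles that are
mostly empty or veinous are removed (a tile is dropped when more than 10%
of its Gaussian-blurred pixels lie strictly above the 90th percentile of
blurred ROI values), and kept tiles are 3×3 block-averaged. For each tile a
moving-window gray-level co-occurrence matrix (GLCM, `n_gray = 4`, pooled
over the 0°/45°/90°/135° shifts) yields seven Haralick-style texture maps:

- mean μ = Σᵢⱼ i·P(i,j), variance = Σᵢⱼ (i−μ)²·P(i,j)
- contrast = Σ (i−j)²·P, dissimilarity = Σ |i−j|·P
- homogeneity = Σ P/(1+(i−j)²), second moment = Σ P², entropy = −Σ P·ln P

Each map is summarized per tile by mean, SD, Q1, Q3, kurtosis and skewness
(42 features), and tiles are embedded with PCA (`prcomp`), optionally
rendered with tile thumbnails at their score coordinates.

**IHC scoring.** Per-cell staining intensities are stratified at marker
cutoffs (F4/80: 0.05/0.4/0.6; CD3: 0.2/0.4/0.6) and summarized per region
as the H-score `1·%low + 2·%moderate + 3·%high` ∈ [0, 300] and percent
positive, optionally restricted to 500×500 vein patches (central vs portal)
and compared across groups by one-way ANOVA.

**Activity score.** Per sample, `score(s) = Σ_up expr[g,s] − Σ_down
expr[g,s]` on log2 normalized expression; lower = less pathway activity.
Includes ortholog mapping of signatures with exclusion reporting and a
reduced-signature sensitivity correlation.

**Expression clustering.** Gene rows are median-centered, clustered with
`1 − Pearson` distance and average linkage (UPGMA), cut into k (default 4)
clusters, and summarized per cluster × experimental group.

## Worked example

```r
library(stainscape)

# simulate a brightfield field with clustered staining and two veins
cfg <- histology_sim_config(cell_count = 1250,
                            clustering_mode = "clustered",
                            cluster_count = 6, cluster_sd_px = 40,
                            vein_count = 2, seed = 7)
sim <- simulate_histology(cfg)

norm  <- normalize_background(sim$image)
tiles <- filter_tiles(tile_roi(norm), norm)
tiles
#> tile_set: 8x8 grid over 1500x1500 ROI at (top=0, left=0)
#>   kept 24 / 64 tiles

feats <- texture_features(norm, tiles)
round(feats[1:2, c("mean_mean", "entropy_mean", "contrast_mean")], 3)
#>   mean_mean entropy_mean contrast_mean
#> 1     2.983        0.035         0.018
#> 2     2.936        0.109         0.062

pca <- fit_pca(feature_matrix(feats))
pca
#> pca_result: 24 tiles x 42 features
#>   explained variance (first 5): 66.3%, 26.4%, 4.4%, 1.5%, 0.6%
```

`kept 24 / 64` reflects the blur filter removing tiles dominated by vein or
empty background — with tightly clustered staining, many tiles of this
field are essentially empty. The per-tile features quantify local texture:
a mean level near 3 (of 0–3) means most pixels are bright background, and
entropy/contrast rise where stain is heterogeneous. Two thirds of the
feature variance falls on PC1, which tracks stain-density features.

H-score scoring from a per-cell table:

```r
cells <- simulate_cell_intensities(c(10, 40, 30, 20),
                                   c(0.025, 0.225, 0.5, 0.7),
                                   sd = 0, seed = 1)
h_score(stratify_cells(cells, cutoff_preset("f480")))
#>   region_id n_cells pct_neg pct_low pct_moderate pct_high h_score
#> 1  region_1     100      10      40           30       20     160
#>   percent_positive
#> 1               90
```

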