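---
title: "Quantifying spatial staining patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial staining patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

stainscape quantifies how immunohistochemical (IHC) staining is arranged in
tissue — not just how much stain there is, but whether stained cells are
dispersed or aggregated, and whether aggregation is localized to particular
structures such as central veins. This vignette explains the models behind
each stage, the tunable parameters and their defaults, the numerical
choices the implementation pins down, and what the synthetic-data tests do
and do not demonstrate about real images.

## The image model and its conventions

All image stages operate on a numeric matrix in `[0, 1]` under brightfield
polarity: high values are bright (empty glass, vein lumina, unstained
tissue), low values are chromogen (DAB) stain. Coordinates are 0-based
`(row, col)` with the origin at the top-left, and all tile and patch bounds
are half-open, so an 8×8 grid partitions its region of interest (ROI)
exactly, with no pixel shared or dropped. Fluorescence-style images (bright
stain on dark background) can pass through the tile filter via its
`invert` flag.

## Background normalization

Slide scans differ in illumination, so absolute intensities are not
comparable across images. Each image is divided by the mean of a 200×200
patch of empty background, after which the background sits at 1.0 by
construction. Patch placement can be manual (a supplied
`background_patch`) or automatic: windows on a half-patch stride are
scored, and the window with minimal variance among the brightest quartile
(bright *and* flat = background) is chosen, with ties resolved by scan
order. Automatic placement is a convenience for batch runs; on unusual
images (e.g. no clean background in view) a manual patch is the safer
choice.

## Tiling and the empty/vein tile filter

The 1500×1500 ROI is cut into an 8×8 grid. Since 1500/8 = 187.5 px is not
an integer, cut positions are `round(i · 187.5)` (half away from zero),
giving boundaries 0, 188, 375, 563, 750, 938, 1125, 1313, 1500 and tiles
that alternate between 187 and 188 px — an exact partition rather than
dropped remainder pixels.

Tiles dominated by vein lumina or empty glass carry no tissue texture and
would contaminate downstream statistics. The filter blurs the ROI with a
Gaussian (σ = 2 px by default), takes the 90th percentile of all blurred
ROI pixels as a brightness cutoff, and drops any tile in which more than
10% of blurred pixels lie *strictly* above the cutoff. Three choices are
pinned here:

- the percentile is computed over the blurred ROI (not per tile, and not on
  the raw image), so the cutoff adapts to each image and the drop set is
  invariant to rescaling the image by a positive constant;
- the inequality at the cutoff is strict, which makes a constant ROI keep
  all 64 tiles (no pixel is strictly above its own percentile);
- the blur is a direct separable spatial convolution with replicate
  boundaries rather than an FFT convolution. FFT round-off spreads
  ~1e-16 ripple across the entire image, and a strict threshold happily
  amplifies that ripple into arbitrary drop decisions; spatial convolution
  keeps constant regions bitwise constant, so the rule is exact.

σ is exposed (`blur_sigma`) because the appropriate smoothing scale depends
on magnification; the default is regression-tested so results are
reproducible. After filtering, kept tiles are 3×3 block-averaged (partial
edge blocks use the mean of available pixels), which suppresses pixel
noise and reduces compute before texture analysis.

## GLCM texture

Each aggregated tile is quantized once into `n_gray = 4` equal-width levels
spanning the tile's own range (a constant tile maps to level 0). Per-tile
range quantization makes texture statistics invariant to additive
intensity shifts, at the cost of making levels tile-relative — a
deliberate trade: texture, not absolute intensity, is the target, and
absolute intensity is captured separately by the normalization step.

For every pixel whose 3×3 window is complete, co-occurrence counts are
accumulated over the four standard shifts (0° = (0,1), 45° = (−1,1),
90° = (−1,0), 135° = (−1,−1)), pooled at the count level into a single
4×4 matrix per window, symmetrized (each pair counted in both directions),
and normalized. Pooling over angles before computing statistics matches
multi-shift texture packages and makes the maps invariant to 90°
rotations of the tile. Seven statistics are evaluated per window: mean,
variance, contrast, dissimilarity, homogeneity, angular second moment and
entropy (natural log by default, base-2 available). Border pixels with
incomplete windows are masked, not zero-filled.

The window size (3×3) is configurable; larger windows smooth the maps and
shrink the valid interior. The implementation computes all windows at once
with summed-area tables over per-shift pair-code indicator images, and is
tested for exact equality against a brute-force per-window enumeration
oracle, including exhaustively on all 512 binary 3×3 images.

Each of the seven maps is summarized over valid pixels by mean, sample SD,
Q1, Q3 (type-7 linear-interpolation quantiles), excess kurtosis and moment
skewness *g*₁ (both via e1071, type 1), yielding 42 features per tile.
Degenerate maps (zero variance) produce flagged `NaN` moments rather than
silent zeros — a zero would fake signal where there is none; flagged tiles
are dropped (and counted) when the feature matrix is assembled. Quantile
and kurtosis conventions differ across software; the ones above are pinned
by tests, and cross-package comparisons should expect convention-level
differences.

## PCA embedding

The tile × 42-feature matrix is centered and, by default, scaled to unit
variance before `prcomp`. Scaling is a consequential choice: entropies
(≈ 0–2.8) and variances live on very different scales, and unscaled PCA is
dominated by whichever feature family happens to have the largest numeric
spread. Both modes are supported; the default is logged in the result
(`scale` field). Loading signs are fixed deterministically (the
largest-magnitude entry of each loading column is positive) so scores and
figures are reproducible across runs and platforms. For interpretation,
a thumbnail scatter places the k most extreme tiles per quadrant (by
distance from the origin) at their PC1/PC2 coordinates.

## H-score and vein patches

Per-cell mean stain intensities are stratified at marker-specific cutoffs
(F4/80: low 0.05, medium 0.4, high 0.6; CD3: 0.2/0.4/0.6; units are the
optical-density-like scale of the upstream cell detection). A cell exactly
at a cutoff enters the *higher* stratum; this boundary convention is not
universal and is pinned by tests. Per region,

H = 1·%low + 2·%moderate + 3·%high ∈ [0, 300],

and percent positive = 100 − %neg. Zone-specific scoring restricts cells
to 500×500 px patches centered on central or portal veins before scoring;
patches may overlap (logged), and empty regions or patches are skipped
with a warning rather than scored as zero. Group comparison is a classical
fixed-effects one-way ANOVA on region-level H-scores, with no nesting of
regions within animals; truly degenerate inputs (all scores identical) are
flagged rather than given a fabricated F. The test suite calibrates the
test under a simulated null (1000 replicates, 4 groups × 7 regions): the
type-I error at α = 0.05 must land in [0.03, 0.07].

Cell *detection* — segmentation and optical-density measurement on the
slide — is out of scope; the package starts from the per-cell table those
tools export.

## Activity score

The signature activity score is the raw signed sum of log2 normalized
expression: up-genes weighted +1, down-genes −1, so lower scores mean less
pathway activity. No per-gene centering is applied by default — the raw
sum is what the score definition states — which means highly expressed
genes dominate; an optional per-gene z-scoring mode is provided for
analyses where that dominance is unwanted. Signature genes absent from a
matrix are skipped, never imputed, and the coverage fraction is attached
to every result so scores from different matrices are comparable with eyes
open.

Cross-species use maps the signature through a user-supplied two-column
ortholog table (many-to-one allowed, duplicates collapsed); genes without
an ortholog are excluded and the exclusion fraction reported, and a target
mapped into both the up and down sets is removed from both. The
`sensitivity_check` quantifies the effect of such exclusions as the
Pearson correlation between full- and reduced-signature score vectors. On
simulated data with a planted signature, removing a random 6% of signature
genes leaves r > 0.9 — in practice far higher, because the score is a sum
of hundreds of terms and removing 6% of them perturbs it little.

## Expression clustering

Gene rows are median-centered across samples (median, not mean, for
robustness to single-sample outliers), then clustered with distance
`1 − Pearson` and average linkage (UPGMA via `hclust`), and cut into k
clusters (default 4, the number of qualitatively distinct
genotype-by-treatment patterns the design can support; k is a required
modeling choice, not estimated). Zero-variance rows are removed first —
Pearson correlation is undefined for them — and reported. Cluster labels
are deterministic: ordered by decreasing size with ties broken by the
smallest member gene identifier. The implementation is verified against a
naive O(n³) UPGMA that recomputes every average inter-cluster distance
from the original distance matrix, by comparing cophenetic matrices
exactly for n ≤ 12.

## The synthetic generators: what they emulate, and what they do not

The generators exist so every stage has a testable input with known ground
truth; their defaults were chosen once, as plausible values for an
F4/80-stained liver section at ~0.5 µm/px, and are not fitted to any data.

**Histology** (`simulate_histology`): dark anti-aliased disks (radius 6 px,
darkness = `stain_intensity` scaled by one of four staining strata) on a
bright background (0.9), optional bright cell-free vein disks (radius
150 px, comparable to a tile), additive Gaussian noise (sd 0.02) clipped
to `[0, 1]` with the clipped fraction reported. Cell placement is uniform
(dispersed) or a Thomas process — uniform parents, Gaussian offspring —
because the Thomas process reduces "how aggregated" to a single
interpretable knob, the offspring sd. Disks rather than Gaussian blobs
keep the stained area crisply bounded, which is what the tile filter must
discriminate. The PCA-separation experiment fixes three study conditions:
sparse dispersed (250 cells), dense dispersed (1250), and clustered dense
(1250 cells, 6 clusters, sd 40 px), 20 images each.

What the simulation does *not* model: RGB DAB/hematoxylin chemistry and
stain deconvolution (grayscale only), counterstain texture, uneven
illumination, sectioning artifacts, or biologically realistic cell shapes.
Passing tests demonstrate that the pipeline's statistics respond to
density and aggregation as designed — not that they are optimal
discriminators on real slides, where staining variability and tissue
architecture add variance the simulation lacks.

**Cell tables** (`simulate_cell_intensities`): four Gaussian strata with
configurable means and counts, truncated at zero; with sd = 0, threshold
stratification recovers the configured fractions exactly, which anchors
the H-score tests.

**Expression** (`simulate_expression`): a genes × samples log2 matrix over
the 2×2 genotype (NTC/sgBap1) × treatment (Veh/CCl4) design, with per-gene
baselines ~N(8, 1.5), a planted up/down signature (up-genes +2 in
high-activity groups, down-genes +2 in low-activity groups, so the signed
sum separates genotypes by construction), 400 interaction genes following
four per-group templates — damage-induced-but-blunted, immune
pre-activation, control-only regulators, knockout-only metabolic — and
Gaussian noise (sd 0.5 by default; 0.1 in recovery tests, well below the
template separation of ~2). Expression is generated directly on the log2
scale; no read-level simulation.

## Problem sizes and determinism

All generators are bit-reproducible given a seed (RNG state is restored
afterwards). The heaviest routine check — 60 simulated 1500×1500 images
through normalization, filtering, texture and PCA, with a ground-truth
silhouette in (PC1, PC2) required to exceed 0.25 — runs in a couple of
minutes on one CPU; the GLCM oracle comparison covers all 512 binary 3×3
images and 100 random 8×8 images exactly. These sizes were chosen so the
whole suite is routinely runnable while still exercising every stage at
full image scale.

## Known limitations

- The ROI and background patch are placed by the caller (or a simple
  automatic heuristic); there is no tissue detection.
- Texture features are computed at a single resolution; no multiscale
  pyramid.
- The ANOVA treats regions as independent; repeated regions per animal
  would need a mixed model, which is out of scope.
- The activity score's raw sum is intentionally scale-sensitive; use the
  z-scoring mode when gene-level scale dominance is a concern.
- The 4-cluster cut is a fixed modeling choice; no cluster-number
  selection criterion is applied.
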