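Package: stainscape
Title: Quantitative Texture, Staining and Signature Analysis for IHC and
    Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify spatial patterning of immunohistochemical
    (IHC) staining and matched bulk expression readouts in tissue studies.
    Implements a tile-based gray-level co-occurrence matrix (GLCM) texture
    pipeline for brightfield IHC images (background normalization, 8x8
    tiling of a 1500x1500 region of interest, blur-based exclusion of empty
    or veinous tiles, 3x3 aggregation, moving-window Haralick texture maps
    and per-tile summary features, PCA embedding), per-cell H-score and
    percent-positive IHC scoring with vein-patch restriction and one-way
    ANOVA group comparison, a signed-sum gene-signature activity score with
    ortholog filtering and a reduced-set sensitivity check, and
    correlation-distance average-linkage clustering of median-centered
    expression profiles. Synthetic generators for histology images, per-cell
    intensity tables and expression matrices with planted ground truth make
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    cluster,
    mclust,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
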