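# GLCM engine: quantization, co-occurrence vs brute-force enumeration,
# Haralick statistics, moving-window maps vs a windowed oracle, invariances
# and tile summaries.

test_that("quantization uses equal-width bins with clamped maximum", {
  x <- matrix(c(0, 1 / 3, 2 / 3, 1), 2, 2)
  expect_identical(sort(as.vector(quantize(x, 4))), 0:3)
  expect_true(all(quantize(matrix(5, 3, 3), 4) == 0L))
  set.seed(1)
  r <- matrix(runif(100), 10, 10)
  expect_true(all(quantize(r, 4) <= 3L))
  # max maps to n_gray - 1, never n_gray
  expect_equal(max(quantize(r, 4)[which.max(r)]), 3L)
})

test_that("co-occurrence matches hand enumeration and normalizes to 1", {
  lv <- rbind(c(0L, 0L), c(1L, 1L))
  P <- cooccurrence(lv, c(0, 1), n_gray = 2)
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(sum(P), 1)
  # constant levels: single nonzero entry
  Pc <- cooccurrence(matrix(0L, 3, 3), c(0, 1), n_gray = 4)
  expect_equal(Pc[1, 1], 1)
  expect_equal(sum(Pc), 1)
  expect_error(cooccurrence(matrix(0L, 1, 1), c(0, 1), n_gray = 2),
               "no pixel pairs")
})

test_that("co-occurrence equals the enumeration oracle on all binary 3x3 images", {
  shifts <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (id in 0:511) {
    lv <- matrix(as.integer(intToBits(id)[1:9]), 3, 3)
    for (s in shifts) {
      for (sym in c(TRUE, FALSE)) {
        expect_equal(cooccurrence(lv, s, n_gray = 2, symmetric = sym),
                     oracle_cooccurrence(lv, s, 2, symmetric = sym),
                     tolerance = 1e-14)
      }
    }
  }
})

test_that("the seven statistics match their closed forms", {
  # degenerate distribution
  P0 <- matrix(0, 4, 4); P0[1, 1] <- 1
  st <- glcm_statistics(P0)
  expect_equal(unname(st), c(0, 0, 0, 0, 1, 1, 0))

  # two-point diagonal distribution, derived by direct formula evaluation
  P <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  st2 <- glcm_statistics(P)
  expect_equal(st2[["mean"]], 0.5)
  expect_equal(st2[["variance"]], 0.25)
  expect_equal(st2[["contrast"]], 0)
  expect_equal(st2[["dissimilarity"]], 0)
  expect_equal(st2[["homogeneity"]], 1)
  expect_equal(st2[["second_moment"]], 0.5)
  expect_equal(st2[["entropy"]], log(2))

  # uniform over 4x4
  Pu <- matrix(1 / 16, 4, 4)
  stu <- glcm_statistics(Pu)
  expect_equal(stu[["second_moment"]], 1 / 16)
  expect_equal(stu[["entropy"]], log(16))

  # log2 entropy option
  expect_equal(glcm_statistics(Pu, log_base = "log2")[["entropy"]], 4)

  # agreement with the loop oracle on random distributions
  set.seed(3)
  for (i in 1:20) {
    Q <- matrix(rexp(16), 4, 4); Q <- Q / sum(Q)
    expect_equal(glcm_statistics(Q), oracle_glcm_stats(Q),
                 tolerance = 1e-12)
  }
})

test_that("moving-window maps equal the brute-force windowed oracle", {
  # vertical stripes: columns alternate between the extreme levels
  stripes <- matrix(rep(c(0, 1), length.out = 6), 6, 6, byrow = TRUE)
  tm <- texture_map(stripes, glcm_config())
  or <- oracle_texture_map(stripes)
  for (nm in names(tm$maps))
    expect_equal(tm$maps[[nm]], or[[nm]], tolerance = 1e-12)
  # interior contrast constant on the stripe pattern
  inner <- tm$maps$contrast[2:5, 2:5]
  expect_true(all(abs(inner - inner[1, 1]) < 1e-12))

  # random tiles, both window sizes
  set.seed(11)
  for (rep in 1:5) {
    tile <- matrix(runif(81), 9, 9)
    tm2 <- texture_map(tile, glcm_config())
    or2 <- oracle_texture_map(tile)
    for (nm in names(tm2$maps))
      expect_equal(tm2$maps[[nm]], or2[[nm]], tolerance = 1e-12)
  }
  tile5 <- matrix(runif(121), 11, 11)
  tm5 <- texture_map(tile5, glcm_config(window = 5))
  or5 <- oracle_texture_map(tile5, window = 5)
  for (nm in names(tm5$maps))
    expect_equal(tm5$maps[[nm]], or5[[nm]], tolerance = 1e-12)
})

test_that("constant tiles give the closed-form texture limits everywhere", {
  tm <- texture_map(matrix(0.4, 8, 8), glcm_config())
  v <- tm$valid
  expect_true(all(tm$maps$homogeneity[v] == 1))
  expect_true(all(tm$maps$entropy[v] == 0))
  expect_true(all(tm$maps$contrast[v] == 0))
  expect_true(all(tm$maps$dissimilarity[v] == 0))
  expect_true(all(tm$maps$variance[v] == 0))
  expect_true(all(tm$maps$second_moment[v] == 1))
  # border is masked
  expect_true(all(is.na(tm$maps$mean[!v])))
})

test_that("texture is invariant to intensity offset and 90-degree rotation", {
  set.seed(21)
  tile <- matrix(runif(100), 10, 10)
  tm <- texture_map(tile, glcm_config())
  tm_off <- texture_map(tile + 3.7, glcm_config())
  for (nm in names(tm$maps))
    expect_equal(tm$maps[[nm]], tm_off$maps[[nm]], tolerance = 1e-12)

  rot90 <- function(m) t(apply(m, 2, rev))
  tm_rot <- texture_map(rot90(tile), glcm_config())
  for (nm in names(tm$maps))
    expect_equal(tm_rot$maps[[nm]], rot90(tm$maps[[nm]]), tolerance = 1e-12)
})

test_that("windowed maps differ from whole-tile statistics except in the limit", {
  set.seed(31)
  tile <- matrix(runif(81), 9, 9)
  cfg <- glcm_config()
  tm <- texture_map(tile, cfg)
  # pooled whole-tile co-occurrence at the count level
  lv <- quantize(tile, 4)
  counts <- matrix(0, 4, 4)
  for (s in cfg$shifts) {
    npair <- (nrow(lv) - abs(s[1])) * (ncol(lv) - abs(s[2]))
    counts <- counts + cooccurrence(lv, s, n_gray = 4) * (2 * npair)
  }
  pooled <- glcm_statistics(counts / sum(counts))
  per_map_mean <- sapply(tm$maps, function(m) mean(m[tm$valid]))
  # windowing matters: per-map means do not collapse to the pooled stats
  expect_gt(max(abs(per_map_mean - pooled[names(per_map_mean)])), 1e-3)

  # limit equivalence: window spanning the whole tile reproduces them
  tm_full <- texture_map(tile, glcm_config(window = 9))
  center <- sapply(tm_full$maps, function(m) m[5, 5])
  expect_equal(center, pooled[names(center)], tolerance = 1e-12)
})

test_that("statistic ranges hold on random tiles", {
  set.seed(41)
  for (rep in 1:10) {
    tile <- matrix(runif(144), 12, 12)
    tm <- texture_map(tile, glcm_config())
    v <- tm$valid
    expect_true(all(tm$maps$homogeneity[v] > 0 &
                      tm$maps$homogeneity[v] <= 1))
    expect_true(all(tm$maps$second_moment[v] > 0 &
                      tm$maps$second_moment[v] <= 1))
    expect_true(all(tm$maps$entropy[v] >= 0 &
                      tm$maps$entropy[v] <= 2 * log(4) + 1e-12))
    expect_true(all(tm$maps$contrast[v] <= 9 + 1e-12))
  }
})

test_that("per-shift diagnostic mode returns one map set per angle", {
  set.seed(51)
  tile <- matrix(runif(64), 8, 8)
  per <- texture_map(tile, glcm_config(), pool_shifts = FALSE)
  expect_length(per, 4L)
  expect_true(all(vapply(per, inherits, TRUE, "texture_map")))
  # single-shift maps match the oracle restricted to that shift
  o <- oracle_texture_map(tile, shifts = list(c(0, 1)))
  expect_equal(per[["0,1"]]$maps$contrast, o$contrast, tolerance = 1e-12)
})

test_that("tile summaries use type-7 quantiles and flag degenerate moments", {
  fake_map <- function(vals) {
    m <- matrix(NA_real_, 4, 4)
    valid <- matrix(FALSE, 4, 4)
    m[2:3, 2:3] <- vals
    valid[2:3, 2:3] <- TRUE
    structure(list(maps = list(mean = m), valid = valid,
                   config = glcm_config(statistics = "mean")),
              class = "texture_map")
  }
  fv <- summarize_tile(fake_map(c(1, 2, 3, 4)), tile_id = "t")
  expect_equal(fv$mean_mean, 2.5)
  # type-7 interpolation: q1 = 1.75, q3 = 3.25
  expect_equal(fv$mean_q1, 1.75)
  expect_equal(fv$mean_q3, 3.25)
  expect_equal(fv$mean_sd, sd(1:4))
  expect_false(is.nan(fv$mean_skewness))

  # symmetric values have zero skewness
  fvs <- summarize_tile(fake_map(c(-2, -1, 1, 2)))
  expect_lt(abs(fvs$mean_skewness), 1e-12)

  # constant map: sd 0, quartiles equal the constant, moments flagged NaN
  fvc <- summarize_tile(fake_map(rep(0.3, 4)))
  expect_equal(fvc$mean_mean, 0.3)
  expect_equal(fvc$mean_sd, 0)
  expect_equal(fvc$mean_q1, 0.3)
  expect_equal(fvc$mean_q3, 0.3)
  expect_true(is.nan(fvc$mean_kurtosis))
  expect_true(is.nan(fvc$mean_skewness))
  expect_true(fvc$flagged)
})

test_that("texture_features yields 42 named features per kept tile", {
  img <- matrix(runif(1500^2, 0.3, 1), 1500, 1500)
  ts <- tile_roi(img)
  ts$tiles$keep[5:64] <- FALSE  # score only 4 tiles for speed
  tf <- texture_features(img, ts)
  expect_equal(nrow(tf), 4L)
  expect_true(all(texture_feature_names() %in% names(tf)))
  expect_length(texture_feature_names(), 42L)
})
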