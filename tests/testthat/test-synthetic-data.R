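# Synthetic generators: determinism, ground-truth contracts, spatial
# clustering behavior.

test_that("histology generator handles the no-cell case and stays in [0,1]", {
  cfg <- histology_sim_config(image_size = 300, cell_count = 0,
                              noise_sd = 0.02, seed = 3)
  sim <- simulate_histology(cfg)
  expect_equal(nrow(sim$cells), 0L)
  expect_true(all(sim$image >= 0 & sim$image <= 1))
  # background_level everywhere, up to noise
  expect_lt(max(abs(sim$image - cfg$background_level)), 6 * cfg$noise_sd)
  expect_true(is.numeric(sim$clip_fraction))

  # noiseless, cell-free image is exactly constant
  sim0 <- simulate_histology(histology_sim_config(image_size = 100,
                                                  cell_count = 0,
                                                  noise_sd = 0, seed = 1))
  expect_true(all(sim0$image == 0.9))
  expect_identical(sim0$clip_fraction, 0)
})

test_that("histology generator is bit-identical for identical seed/config", {
  cfg <- histology_sim_config(image_size = 400, cell_count = 150,
                              vein_count = 1, vein_radius_px = 60, seed = 11)
  a <- simulate_histology(cfg)
  b <- simulate_histology(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$cells, b$cells)
  expect_identical(a$veins, b$veins)
})

test_that("clustered mode yields smaller nearest-neighbor distances", {
  nn_mean <- function(cells) {
    d <- as.matrix(dist(cbind(cells$x, cells$y)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  disp <- simulate_histology(histology_sim_config(
    image_size = 600, cell_count = 200, seed = 5))
  clus <- simulate_histology(histology_sim_config(
    image_size = 600, cell_count = 200, clustering_mode = "clustered",
    cluster_count = 5, cluster_sd_px = 30, seed = 5))
  expect_lt(nn_mean(clus$cells), nn_mean(disp$cells))
})

test_that("impossible cell packings and bad configs are rejected", {
  expect_error(histology_sim_config(image_size = 100, cell_count = 500,
                                    cell_radius_px = 10),
               "cannot fit")
  expect_error(histology_sim_config(cell_radius_px = 800),
               "image_size/2")
  expect_error(histology_sim_config(clustering_mode = "clustered",
                                    cluster_count = 0),
               "cluster_count")
})

test_that("vein interiors are bright, cell-free and recorded in the mask", {
  cfg <- histology_sim_config(image_size = 500, cell_count = 300,
                              vein_count = 1, vein_radius_px = 80,
                              noise_sd = 0, seed = 2)
  sim <- simulate_histology(cfg)
  expect_false(is.null(sim$vein_mask))
  expect_true(all(sim$image[sim$vein_mask] == cfg$background_level))
  v <- sim$veins
  d2 <- (sim$cells$x - v$x[1])^2 + (sim$cells$y - v$y[1])^2
  expect_true(all(d2 > v$radius[1]^2))
})

test_that("cell-intensity generator respects strata, sd and determinism", {
  # all cells in one stratum
  tab <- simulate_cell_intensities(c(10, 0, 0, 0),
                                   c(0.02, 0.2, 0.5, 0.7), sd = 0.01,
                                   seed = 1)
  expect_equal(nrow(tab), 10L)
  expect_true(all(tab$true_stratum == "neg"))

  # sd = 0 reproduces stratum means exactly
  tab0 <- simulate_cell_intensities(c(3, 4, 5, 6),
                                    c(0.02, 0.2, 0.5, 0.7), sd = 0, seed = 1)
  expect_identical(as.numeric(tapply(tab0$intensity, tab0$true_stratum,
                                     unique)
                              [c("neg", "low", "moderate", "high")]),
                   c(0.02, 0.2, 0.5, 0.7))

  # midpoint cutoffs recover every label when sd is small vs spacing
  cuts <- intensity_cutoffs(0.11, 0.35, 0.6)
  tab2 <- simulate_cell_intensities(c(25, 25, 25, 25),
                                    c(0.02, 0.2, 0.5, 0.7), sd = 0.01,
                                    seed = 42)
  lab <- stratify_cells(tab2, cuts)
  expect_identical(as.character(lab$stratum),
                   as.character(lab$true_stratum))

  expect_identical(simulate_cell_intensities(c(5, 5, 5, 5),
                                             c(0.02, 0.2, 0.5, 0.7),
                                             sd = 0.05, seed = 9),
                   simulate_cell_intensities(c(5, 5, 5, 5),
                                             c(0.02, 0.2, 0.5, 0.7),
                                             sd = 0.05, seed = 9))
  expect_error(simulate_cell_intensities(c(-1, 0, 0, 0),
                                         c(0.02, 0.2, 0.5, 0.7)),
               "nonnegative")
  expect_error(simulate_cell_intensities(c(1, 1, 1, 1),
                                         c(0.5, 0.2, 0.6, 0.7)),
               "increasing")
})

test_that("expression generator plants signature and interaction structure", {
  # noiseless, no interaction genes: non-signature rows constant
  cfg <- expression_sim_config(n_genes = 60, n_signature_up = 10,
                               n_signature_down = 10,
                               n_interaction_genes = 0, noise_sd = 0,
                               seed = 4)
  sim <- simulate_expression(cfg)
  bg <- sim$truth$gene[sim$truth$role == "background"]
  expect_true(all(apply(sim$expr[bg, ], 1, function(r) length(unique(r))) ==
                    1L))

  # zero effect: scores identical across genotypes by construction
  cfg0 <- expression_sim_config(n_genes = 60, n_signature_up = 10,
                                n_signature_down = 10, signature_effect = 0,
                                n_interaction_genes = 0, noise_sd = 0,
                                seed = 4)
  sim0 <- simulate_expression(cfg0)
  sig <- signature_gene_set(
    sim0$truth$gene[sim0$truth$role == "signature_up"],
    sim0$truth$gene[sim0$truth$role == "signature_down"])
  sc <- activity_score(sim0$expr, sig)
  by_geno <- tapply(sc, sim0$samples$genotype, mean)
  expect_equal(unname(diff(by_geno)), 0)

  # determinism
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))

  # malformed templates rejected
  expect_error(expression_sim_config(interaction_patterns = list(
    c(0, 1), c(0, 1, 2, 3), c(0, 0, 0, 0), c(1, 1, 1, 1))),
    "length 4")
  expect_error(expression_sim_config(n_genes = 10, n_signature_up = 5,
                                     n_signature_down = 5,
                                     n_interaction_genes = 5),
               "exceed")
})

test_that("planted signature separates genotypes in the expected direction", {
  cfg <- expression_sim_config(seed = 8, signature_effect = 2,
                               noise_sd = 0.5)
  sim <- simulate_expression(cfg)
  sig <- signature_gene_set(
    sim$truth$gene[sim$truth$role == "signature_up"],
    sim$truth$gene[sim$truth$role == "signature_down"])
  sc <- activity_score(sim$expr, sig)
  # lower score = less activity in the knockout groups
  expect_lt(mean(sc[sim$samples$genotype == "sgBap1"]),
            mean(sc[sim$samples$genotype == "NTC"]))
})
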