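test_that("generators are pure functions of their seed", {
  a <- make_connectivity_world(n_seed = 24, n_target = 120, n_time = 60,
                               n_subjects = 2, seed = 1)
  b <- make_connectivity_world(n_seed = 24, n_target = 120, n_time = 60,
                               n_subjects = 2, seed = 1)
  expect_identical(a$per_subject_seed, b$per_subject_seed)
  expect_identical(a$truth$latent, b$truth$latent)
  pa <- make_expression_panel(a, n_samples = 10, n_genes = 50, seed = 2)
  pb <- make_expression_panel(b, n_samples = 10, n_genes = 50, seed = 2)
  expect_identical(pa$panel$expression, pb$panel$expression)
  ta <- make_term_maps(a, seed = 3); tb <- make_term_maps(b, seed = 3)
  expect_identical(ta$maps, tb$maps)
  sa <- make_annotation_sets(pa$panel$gene_symbols,
                             pa$tracking_genes$gene[1:3], seed = 4)
  sb <- make_annotation_sets(pb$panel$gene_symbols,
                             pb$tracking_genes$gene[1:3], seed = 4)
  expect_identical(sa$sets, sb$sets)
})

test_that("the planted latent is a spatial axis and drives connectivity", {
  w <- small_world()
  # latent correlates almost perfectly with the y coordinate per hemisphere
  for (h in c("L", "R")) {
    sel <- w$seed_grid$hemisphere == h
    expect_gte(abs(cor(w$truth$latent[sel], w$seed_grid$coords_mm[sel, 2])),
               0.99)
  }
  # in the noise-free limit, same-latent voxels correlate at the clip
  w0 <- make_connectivity_world(n_seed = 16, n_target = 80, n_time = 60,
                                n_subjects = 1, noise_sd = 0, seed = 3)
  ts_s <- concat(w0$per_subject_seed, w0$seed_grid)
  ts_t <- concat(w0$per_subject_target, w0$target_grid)
  fc <- compute_fc_matrix(ts_s, ts_t)
  pair <- which(abs(outer(w0$truth$latent,
                          w0$truth$target_latent, `-`)) < 0.03,
                arr.ind = TRUE)
  expect_gt(nrow(pair), 0)
  expect_gte(min(fc$z_values[pair]), atanh(0.95))
  # FC decays with latent separation: near pairs beat far pairs
  sep <- abs(outer(w0$truth$latent, w0$truth$target_latent, `-`))
  expect_gt(mean(fc$z_values[sep < 0.1]), mean(fc$z_values[sep > 0.5]))
})

test_that("the generated world satisfies downstream preconditions", {
  w <- small_world()
  expect_equal(length(w$truth$latent), n_voxels(w$seed_grid))
  expect_equal(length(w$truth$target_latent), n_voxels(w$target_grid))
  expect_true(all(w$truth$latent >= 0 & w$truth$latent <= 1))
  expect_true(all(w$network_labels %in% names(w$truth$network_centers)))
  expect_true(all(table(w$network_labels) >= 1))   # no empty network
  expect_gte(w$n_time, 50)
  # seed and target grids are disjoint in space
  key <- function(g) apply(g$coords_mm, 1, paste, collapse = ",")
  expect_length(intersect(key(w$seed_grid), key(w$target_grid)), 0L)
  # expression panel: unique genes, finite values, one coordinate per sample
  pan <- make_expression_panel(w, n_samples = 8, n_genes = 40, seed = 5)
  expect_false(anyDuplicated(pan$panel$gene_symbols) > 0)
  expect_true(all(is.finite(pan$panel$expression)))
  expect_equal(nrow(pan$panel$sample_coords_mm), 8L)
  # tracking genes recorded with both signs
  expect_setequal(unique(sign(pan$tracking_genes$beta)), c(-1, 1))
})

test_that("noiseless tracking genes reach |loading| = 1 through the pipeline", {
  w <- small_world()
  g <- world_gradients(w)
  pan <- make_expression_panel(w, n_samples = 12, n_genes = 30,
                               sigma = 0, seed = 6)
  suppressWarnings(
    pls <- pls_gradient_association(pan$panel, g, n_perm = 50, seed = 7))
  track <- pan$tracking_genes$gene
  expect_gte(min(abs(pls$loadings[track])), 0.99)
})

test_that("annotation sets serialize to GMT and round-trip", {
  dir <- withr::local_tempdir()
  genes <- sprintf("G%03d", 1:100)
  sets <- make_annotation_sets(genes, genes[1:10], n_sets = 5,
                               set_size = 12, seed = 8)
  p <- file.path(dir, "sets.gmt")
  write_annotation_sets(sets$sets, p)
  back <- read_annotation_sets(p)
  expect_identical(back, sets$sets)
  expect_equal(length(intersect(sets$sets$planted_set, genes[1:10])), 6L)
})
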