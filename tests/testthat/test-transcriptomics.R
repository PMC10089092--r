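test_that("sample-to-gradient sphere mapping uses a closed 3 mm ball", {
  # 3 mm lattice: a sample at a voxel centre with radius 3 averages that
  # voxel and its six face neighbours
  coords <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4)) * 3
  grid <- voxel_grid(coords)
  gradient <- seq_len(nrow(coords))
  centre <- c(6, 6, 6)
  panel <- expression_panel(matrix(rnorm(3), 1, 3), rbind(centre))
  got <- map_samples_to_gradient(panel, gradient, grid, radius_mm = 3)
  inside <- rowSums(sweep(coords, 2, centre)^2) <= 9 + 1e-9
  expect_equal(sum(inside), 7L)
  expect_equal(got$sample_gradient, mean(gradient[inside]))
  # uniform gradient maps every kept sample to that constant
  pan2 <- expression_panel(matrix(rnorm(6), 2, 3),
                           rbind(c(0, 0, 0), c(12, 12, 12)))
  got2 <- map_samples_to_gradient(pan2, rep(0.7, nrow(coords)), grid, 3)
  expect_equal(got2$sample_gradient, c(0.7, 0.7))
  # out-of-range samples dropped with warning; all dropped is an error
  pan3 <- expression_panel(matrix(rnorm(6), 2, 3),
                           rbind(c(0, 0, 0), c(99, 99, 99)))
  expect_warning(got3 <- map_samples_to_gradient(pan3, gradient, grid, 3),
                 "dropped")
  expect_equal(got3$kept, c(TRUE, FALSE))
  pan4 <- expression_panel(matrix(rnorm(3), 1, 3), rbind(c(99, 99, 99)))
  expect_error(map_samples_to_gradient(pan4, gradient, grid, 3), "no sample")
})

test_that("PLS1 matches its closed form and handles informative genes", {
  set.seed(91)
  y <- rnorm(25)
  # one gene identical to y, the rest exactly zero: scores proportional to y
  X <- cbind(y, matrix(0, 25, 9))
  colnames(X) <- paste0("G", 1:10)
  expect_warning(fit <- pls1_fit(X, y), "constant gene")
  expect_equal(fit$r_scores_gradient, 1, tolerance = 1e-12)
  expect_equal(cor(fit$scores, y), 1, tolerance = 1e-12)
  # closed-form oracle on random instances: scores along X_c X_c' y_c
  for (i in 1:20) {
    set.seed(200 + i)
    n <- sample(10:30, 1); p <- sample(5:60, 1)
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    fit <- pls1_fit(X, y)
    Xc <- scale(X, scale = FALSE)
    direction <- as.vector(Xc %*% crossprod(Xc, y - mean(y)))
    direction <- direction / sqrt(sum(direction^2))
    got <- fit$scores / sqrt(sum(fit$scores^2))
    expect_lt(min(max(abs(got - direction)), max(abs(got + direction))),
              1e-8)
    expect_gte(fit$r_scores_gradient, 0)       # sign convention
    # loadings equal an independent per-gene Pearson computation
    oracle <- apply(X, 2, function(col) cor(col, fit$scores))
    expect_lt(max(abs(unname(fit$loadings) - oracle)), 1e-12)
  }
  expect_error(pls1_fit(matrix(rnorm(4), 2, 2), rnorm(2)), "3 samples")
  expect_error(pls1_fit(matrix(rnorm(30), 10, 3), rep(1, 10)), "constant")
})

test_that("PLS1 scores are invariant to shifting gene columns", {
  set.seed(92)
  X <- matrix(rnorm(20 * 15), 20)
  y <- rnorm(20)
  a <- pls1_fit(X, y)
  b <- pls1_fit(sweep(X, 2, runif(15, -5, 5), `+`), y)
  expect_lt(max(abs(a$scores - b$scores)), 1e-8)
})

test_that("PLS1 component agrees with an established PLS implementation", {
  set.seed(93)
  X <- matrix(rnorm(25 * 30), 25)
  colnames(X) <- paste0("G", 1:30)
  y <- rnorm(25)
  fit <- pls1_fit(X, y, scale = TRUE)
  ref <- mixOmics::pls(X, y, ncomp = 1, scale = TRUE, mode = "regression")
  ref_scores <- as.vector(ref$variates$X[, 1])
  expect_gt(abs(cor(fit$scores, ref_scores)), 1 - 1e-10)
})

test_that("gene loadings hit the exact sign cases", {
  set.seed(94)
  scores <- rnorm(25)
  X <- cbind(a = scores, b = -scores, c = rnorm(25), d = rep(2, 25))
  suppressWarnings(l <- gene_loadings(X, scores))
  expect_equal(unname(l["a"]), 1, tolerance = 1e-12)
  expect_equal(unname(l["b"]), -1, tolerance = 1e-12)
  expect_equal(unname(l["d"]), 0)
  expect_lt(abs(l["c"]), 0.6)
})

test_that("permutation p matches the exhaustive null at n = 5", {
  set.seed(95)
  X <- matrix(rnorm(5 * 12), 5)
  y <- rnorm(5)
  ex <- pls_permutation_test(X, y, exhaustive = TRUE)
  expect_equal(ex$n_perm, 120L)
  # independent enumeration: refit per permutation via the exported fit
  perms <- fcgradients:::all_permutations(5)
  r_obs <- pls1_fit(X, y)$r_scores_gradient
  rn <- apply(perms, 1, function(p) pls1_fit(X, y[p])$r_scores_gradient)
  expect_equal(ex$p_perm, mean(rn >= r_obs - 1e-15))
  # seeded sampled runs are reproducible
  a <- pls_permutation_test(X, y, n_perm = 300, seed = 4)
  b <- pls_permutation_test(X, y, n_perm = 300, seed = 4)
  expect_identical(a$p_perm, b$p_perm)
})

test_that("top-quartile gene selection follows the floor rule", {
  l <- c(seq(0.01, 1, length.out = 100), seq(-1, -0.001, length.out = 57))
  names(l) <- paste0("G", seq_along(l))
  sel <- select_contributing_genes(l, 0.25)
  expect_length(sel$pls_plus, 25L)             # floor(0.25 * 100)
  expect_length(sel$pls_minus, 14L)            # floor(0.25 * 57)
  # PLS+ holds exactly the 25 largest positive loadings
  expect_setequal(sel$pls_plus, names(sort(l[l > 0], decreasing = TRUE))[1:25])
  expect_setequal(sel$pls_minus, names(sort(l[l < 0]))[1:14])
  expect_length(intersect(sel$pls_plus, sel$pls_minus), 0L)
  # the canonical 5013-gene panel split: 1988 positive -> 497, 3025 negative -> 756
  big <- c(runif(1988, 0.01, 1), -runif(3025, 0.01, 1))
  names(big) <- paste0("g", seq_along(big))
  selb <- select_contributing_genes(big, 0.25)
  expect_length(selb$pls_plus, 497L)
  expect_length(selb$pls_minus, 756L)
  # zero loadings belong to neither pool; degenerate signs warn
  selz <- select_contributing_genes(c(a = 0.5, b = 0.4, c = 0.3, d = 0.2,
                                      e = -0.9))
  expect_equal(selz$pls_plus, "a")
  expect_warning(sneg <- select_contributing_genes(c(a = -1, b = -2)),
                 "PLS\\+ empty")
  expect_length(sneg$pls_plus, 0L)
  # selection invariant to gene reordering
  perm <- sample(seq_along(l))
  sel2 <- select_contributing_genes(l[perm], 0.25)
  expect_setequal(sel2$pls_plus, sel$pls_plus)
  expect_error(select_contributing_genes(l, 1.2), "top_fraction")
})

test_that("planted tracking genes dominate the loading ranks", {
  w <- small_world()
  g <- world_gradients(w)
  pan <- make_expression_panel(w, seed = 96)
  # panel-level recovery against the planted latent itself
  fit <- pls1_fit(pan$panel$expression, pan$sample_latent)
  expect_gte(fit$r_scores_gradient, 0.8)
  # and end to end through the sphere mapping and recovered gradient
  pls <- pls_gradient_association(pan$panel, g, n_perm = 200, seed = 5)
  expect_gte(pls$r_scores_gradient, 0.8)
  track <- pan$tracking_genes$gene
  topdec <- names(sort(abs(pls$loadings),
                       decreasing = TRUE))[seq_len(length(track))]
  expect_gte(mean(topdec %in% track), 0.8)
  # positive-beta genes land in PLS+ or PLS- coherently with the gradient
  plus_beta <- pan$tracking_genes$gene[pan$tracking_genes$beta > 0]
  in_plus <- mean(plus_beta %in% pls$pls_plus)
  in_minus <- mean(plus_beta %in% pls$pls_minus)
  expect_gt(max(in_plus, in_minus), 0.8)
})
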