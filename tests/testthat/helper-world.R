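# Shared fixtures, built once per test run.  All are pure functions of
# fixed seeds.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small world for cheap structural tests
small_world <- function() {
  cached("small", function()
    make_connectivity_world(n_seed = 48L, n_target = 280L, n_time = 80L,
                            n_subjects = 2L, seed = 11L))
}

# the default study-condition world (seed 42)
default_world <- function() {
  cached("default", function() make_connectivity_world())
}

concat <- function(blocks, grid) standardize_and_concatenate(blocks, grid)

world_gradients <- function(world, retain_fraction = 0.10) {
  key <- sprintf("grad_%s_%g", substr(digest_key(world), 1, 8),
                 retain_fraction)
  cached(key, function() {
    ts_s <- concat(world$per_subject_seed, world$seed_grid)
    ts_t <- concat(world$per_subject_target, world$target_grid)
    run_gradient_pipeline(ts_s, ts_t, retain_fraction = retain_fraction)
  })
}

digest_key <- function(world) {
  paste0(n_voxels(world$seed_grid), "_", n_voxels(world$target_grid), "_",
         world$truth$seeds[["master"]])
}

# random connected symmetric non-negative affinity for eigen-oracle tests
random_affinity <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n)
  w <- (m + t(m)) / 2 + 0.05       # strictly positive => connected
  diag(w) <- 1
  w
}

# independent diffusion-map oracle: dense eigendecomposition of the
# alpha-normalized Markov matrix itself (non-symmetric route)
oracle_embedding <- function(W, alpha = 0.5, n_components = 5L) {
  d <- rowSums(W)
  W1 <- W * outer(d^-alpha, d^-alpha)
  d1 <- rowSums(W1)
  P <- W1 / d1
  eg <- eigen(P)
  ord <- order(Re(eg$values), decreasing = TRUE)
  lambda <- Re(eg$values)[ord]
  vec <- Re(eg$vectors)[, ord, drop = FALSE]
  # normalize as psi' D1 psi = 1, matching the diffusion-map convention
  for (k in seq_len(ncol(vec)))
    vec[, k] <- vec[, k] / sqrt(sum(d1 * vec[, k]^2))
  list(lambda = lambda[-1L][seq_len(n_components)],
       coords = sweep(vec[, -1L, drop = FALSE][, seq_len(n_components),
                                               drop = FALSE],
                      2L, lambda[-1L][seq_len(n_components)], `*`))
}

# sign/scale agnostic comparison of two coordinate columns
max_coord_diff <- function(a, b) {
  min(max(abs(a - b)), max(abs(a + b)))
}
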