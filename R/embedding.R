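# Diffusion-map embedding of a connectivity affinity matrix.
#
# The anisotropy parameter alpha controls how strongly the sampling density
# on the underlying manifold influences the embedding (alpha = 0 maximal
# influence, alpha = 1 none); alpha = 0.5 is the convention for brain
# connectivity data and the default throughout.

#' Diffusion-map embedding gradients of an affinity matrix
#'
#' Computes the diffusion-map embedding of a symmetric non-negative affinity
#' matrix W:
#' density normalization `W' = D^-alpha W D^-alpha` with `D = diag(rowSums(W))`,
#' Markov matrix `P` = row-normalized `W'`, eigendecomposition of `P` through
#' its symmetric conjugate, discarding the trivial constant eigenvector
#' (eigenvalue 1).  Component k's per-voxel coordinate is
#' `lambda_k * psi_k` (one-step diffusion-time scaling), components ordered
#' by decreasing eigenvalue; component 1 is the dominant gradient.  Variance
#' explained of component k is `lambda_k / sum(lambda_j)` over all positive
#' non-trivial eigenvalues.
#'
#' Eigenvector signs are arbitrary; a deterministic convention is applied:
#' each component is flipped so its skewness is positive, falling back (for
#' |skewness| < 1e-12) to making the maximum-magnitude voxel positive.
#'
#' @param affinity an `affinity_matrix` or a plain symmetric non-negative
#'   matrix.
#' @param alpha anisotropic-diffusion normalization parameter in [0, 1];
#'   default 0.5.
#' @param n_components number of non-trivial components to retain
#'   (default 10).
#' @return An object of class `gradient_set`: `coordinates` (voxel x
#'   n_components; column 1 = dominant gradient), `eigenvalues`,
#'   `variance_explained`, `alpha`, `n_components`, `grid` (if the input
#'   carried one).
#' @export
diffusion_embedding <- function(affinity, alpha = 0.5, n_components = 10L) {
  grid <- NULL
  if (inherits(affinity, "affinity_matrix")) {
    grid <- affinity$grid
    W <- affinity$values
  } else W <- as.matrix(affinity)
  n <- nrow(W)
  if (ncol(W) != n || max(abs(W - t(W))) > 1e-8)
    stop("affinity must be a symmetric matrix")
  if (any(W < 0)) stop("affinity must be non-negative")
  if (n_components >= n)
    stop("n_components must be smaller than the number of voxels")
  W <- (W + t(W)) / 2

  d <- rowSums(W)
  if (any(d == 0)) stop("affinity has isolated voxels (zero row sums)")
  da <- d^(-alpha)
  W1 <- W * (da %o% da)
  d1 <- rowSums(W1)
  # symmetric conjugate S = D1^-1/2 W' D1^-1/2 shares eigenvalues with P
  s <- 1 / sqrt(d1)
  S <- W1 * (s %o% s)
  eg <- eigen(S, symmetric = TRUE)
  lambda <- eg$values
  if (sum(lambda > 1 - 1e-10) > 1L)
    stop(paste("affinity graph appears disconnected (repeated unit",
               "eigenvalues); densify the affinity before embedding"))
  psi <- eg$vectors * s          # right eigenvectors of P, psi' D1 psi = I
  # drop the trivial stationary component (lambda ~ 1, constant psi)
  lambda <- lambda[-1L]
  psi <- psi[, -1L, drop = FALSE]
  keep <- seq_len(n_components)
  coords <- sweep(psi[, keep, drop = FALSE], 2L, lambda[keep], `*`)
  coords <- fix_component_signs(coords)
  pos <- lambda[lambda > 0]
  ve <- ifelse(lambda[keep] > 0, lambda[keep] / sum(pos), 0)
  structure(
    list(coordinates = coords, eigenvalues = lambda[keep],
         variance_explained = ve, alpha = alpha,
         n_components = as.integer(n_components), grid = grid),
    class = "gradient_set")
}

# deterministic sign convention: positive skewness, else positive extremum
fix_component_signs <- function(coords) {
  for (k in seq_len(ncol(coords))) {
    v <- coords[, k]
    m2 <- mean((v - mean(v))^2)
    sk <- if (m2 > 0) mean((v - mean(v))^3) / m2^1.5 else 0
    flip <- if (abs(sk) >= 1e-12) sk < 0 else v[which.max(abs(v))] < 0
    if (flip) coords[, k] <- -v
  }
  coords
}

#' The dominant gradient of a gradient set
#' @param x a `gradient_set`.
#' @param component which component (default 1, the dominant gradient).
#' @return numeric per-voxel gradient values.
#' @export
dominant_gradient <- function(x, component = 1L) {
  stopifnot(inherits(x, "gradient_set"))
  x$coordinates[, component]
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf(
    "<gradient_set> %d voxels, %d components (alpha = %g)\n",
    nrow(x$coordinates), x$n_components, x$alpha))
  cat(sprintf("  dominant gradient variance explained: %.1f%%\n",
              100 * x$variance_explained[1L]))
  invisible(x)
}

#' @export
summary.gradient_set <- function(object, ...) {
  out <- data.frame(component = seq_len(object$n_components),
                    eigenvalue = object$eigenvalues,
                    variance_explained = object$variance_explained)
  class(out) <- c("summary.gradient_set", "data.frame")
  out
}

#' Scree-style plot of variance explained, plus the dominant-gradient
#' distribution
#' @param x a `gradient_set`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.gradient_set <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::barplot(100 * x$variance_explained,
                    names.arg = seq_len(x$n_components),
                    xlab = "component", ylab = "variance explained (%)", ...)
  graphics::hist(x$coordinates[, 1L], main = "",
                 xlab = "dominant gradient value")
  invisible(x)
}

#' Run the full gradient pipeline on group time series
#'
#' Chains [compute_fc_matrix()], [sparsify_rows()], [cosine_affinity()] and
#' [diffusion_embedding()].
#'
#' @param seed,targets `group_timeseries` objects (see
#'   [standardize_and_concatenate()]).
#' @param retain_fraction row-sparsification fraction (default 0.10).
#' @param alpha diffusion anisotropy parameter (default 0.5).
#' @param n_components retained components (default 10).
#' @param keep_intermediates if `TRUE`, attach the connectivity and affinity
#'   matrices to the result.
#' @return A `gradient_set` (with `fc`/`affinity` fields when
#'   `keep_intermediates`).
#' @export
run_gradient_pipeline <- function(seed, targets, retain_fraction = 0.10,
                                  alpha = 0.5, n_components = 10L,
                                  keep_intermediates = FALSE) {
  fc <- compute_fc_matrix(seed, targets)
  fcs <- sparsify_rows(fc, retain_fraction)
  aff <- cosine_affinity(fcs)
  g <- diffusion_embedding(aff, alpha = alpha, n_components = n_components)
  if (keep_intermediates) {
    g$fc <- fcs
    g$affinity <- aff
  }
  g
}
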