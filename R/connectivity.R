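# Seed-to-brain connectivity: Fisher-z correlation, row sparsification,
# cosine affinity.

R_CLIP <- 1 - 1e-7

new_connectivity_matrix <- function(z, seed_grid, target_grid,
                                    sparsity = NA_real_) {
  structure(list(z_values = z, seed_grid = seed_grid,
                 target_grid = target_grid, sparsity_applied = sparsity),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d seed x %d target voxels%s\n",
              nrow(x$z_values), ncol(x$z_values),
              if (is.na(x$sparsity_applied)) "" else
                sprintf(", sparsified (retain %.0f%%)",
                        100 * x$sparsity_applied)))
  invisible(x)
}

#' Voxelwise seed-to-target Fisher-z connectivity matrix
#'
#' Pearson correlation between the group-level time course of every seed
#' voxel and every target voxel, Fisher z-transformed (`atanh`) after
#' clipping r to +/-(1 - 1e-7).  Voxels flagged constant in either grid get
#' z = 0 on their rows/columns.
#'
#' @param seed a `group_timeseries` for the seed region.
#' @param targets a `group_timeseries` for the target (e.g. cerebrum
#'   excluding the seed) voxels; must not share voxels with the seed.
#' @return A `connectivity_matrix` (seed x target Fisher-z values).
#' @export
compute_fc_matrix <- function(seed, targets) {
  stopifnot(inherits(seed, "group_timeseries"),
            inherits(targets, "group_timeseries"))
  if (ncol(seed$values) != ncol(targets$values))
    stop("seed and target series must share the time axis")
  key <- function(g) apply(round(g$coords_mm, 6), 1L, paste, collapse = ",")
  if (any(key(seed$grid) %in% key(targets$grid)))
    stop("seed and target grids overlap: target voxels must exclude the seed")
  r <- row_correlation(seed$values, targets$values)
  bad_s <- seed$constant_voxels + 1L
  bad_t <- targets$constant_voxels + 1L
  if (length(bad_s)) r[bad_s, ] <- 0
  if (length(bad_t)) r[, bad_t] <- 0
  r <- pmin(pmax(r, -R_CLIP), R_CLIP)
  new_connectivity_matrix(atanh(r), seed$grid, targets$grid)
}

# Pearson correlation between every row of a and every row of b
row_correlation <- function(a, b) {
  za <- zscore_rows(a); zb <- zscore_rows(b)
  r <- tcrossprod(za, zb) / ncol(a)
  r[attr(za, "constant"), ] <- 0
  r[, attr(zb, "constant")] <- 0
  r
}

#' Row-wise sparsification of a connectivity matrix
#'
#' Per seed-voxel row, negative connections are zeroed first; then only the
#' `ceiling(retain_fraction * n_targets)` largest remaining values are
#' retained and the rest zeroed.  Ties at the cutoff are broken by retaining
#' the lower target index first.  Rows left all-zero (all-negative rows) are
#' kept as zeros with a warning.
#'
#' @param fc a `connectivity_matrix`.
#' @param retain_fraction fraction of connections to retain per row, in
#'   (0, 1); default 0.10.
#' @return The sparsified `connectivity_matrix`.
#' @export
sparsify_rows <- function(fc, retain_fraction = 0.10) {
  stopifnot(inherits(fc, "connectivity_matrix"))
  if (!(retain_fraction > 0 && retain_fraction < 1))
    stop("retain_fraction must be in (0, 1)")
  z <- fc$z_values
  n_targets <- ncol(z)
  k <- ceiling(retain_fraction * n_targets)
  out <- matrix(0, nrow(z), n_targets)
  empty <- 0L
  for (i in seq_len(nrow(z))) {
    v <- z[i, ]
    v[v < 0] <- 0
    if (all(v == 0)) { empty <- empty + 1L; next }
    keep <- order(-v, seq_along(v))[seq_len(k)]
    out[i, keep] <- v[keep]
  }
  if (empty > 0L)
    warning(sprintf("%d all-negative row(s) left entirely zero", empty))
  new_connectivity_matrix(out, fc$seed_grid, fc$target_grid,
                          sparsity = retain_fraction)
}

#' Cosine affinity between connectivity profiles
#'
#' Affinity(i, j) = 1 - cosine distance = dot(row_i, row_j) / (|row_i| |row_j|)
#' over the (sparsified, non-negative) connectivity rows.  Zero-norm rows get
#' affinity 0 to all others and 1 on the diagonal.  The result is symmetric
#' with values in [0, 1].
#'
#' @param fc_sparse a sparsified `connectivity_matrix` with non-negative rows.
#' @return An object of class `affinity_matrix`: `values` (seed x seed) and
#'   `grid`.
#' @export
cosine_affinity <- function(fc_sparse) {
  stopifnot(inherits(fc_sparse, "connectivity_matrix"))
  x <- fc_sparse$z_values
  if (any(x < 0))
    stop("cosine affinity expects non-negative (sparsified) rows")
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  a <- tcrossprod(x / nrm)
  a[zero, ] <- 0; a[, zero] <- 0
  a <- (a + t(a)) / 2
  a[a < 0] <- 0; a[a > 1] <- 1
  diag(a) <- 1
  structure(list(values = a, grid = fc_sparse$seed_grid),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("<affinity_matrix> %d x %d, mean off-diagonal %.3f\n",
              nrow(x$values), ncol(x$values),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}
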