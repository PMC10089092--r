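# Relation of the dominant gradient to intrinsic geometry: distance from the
# gradient peak, and a voxel-shuffle permutation test of the
# gradient-distance correlation.

#' Euclidean distance of every voxel from the gradient peak
#'
#' The peak is the voxel with the maximum gradient value (ties resolved to
#' the lowest voxel id, with a warning); distances are Euclidean in
#' millimetres from the grid coordinates.
#'
#' @param gradient numeric per-voxel gradient values.
#' @param grid the [voxel_grid()] of the values.
#' @return A list with `peak_voxel_id` (0-based), `peak_mm`, and
#'   `distances_mm` (zero only at the peak).
#' @export
distance_from_peak <- function(gradient, grid) {
  stopifnot(length(gradient) == n_voxels(grid))
  if (n_voxels(grid) < 2L) stop("need at least two voxels")
  if (diff(range(gradient)) == 0)
    stop("gradient is constant: no meaningful peak")
  mx <- max(gradient)
  tied <- which(gradient == mx)
  if (length(tied) > 1L)
    warning(sprintf("gradient peak tied across %d voxels; using lowest id",
                    length(tied)))
  peak <- tied[1L]
  dmm <- sqrt(rowSums(
    (grid$coords_mm - rep(grid$coords_mm[peak, ], each = n_voxels(grid)))^2))
  list(peak_voxel_id = grid$voxel_ids[peak],
       peak_mm = grid$coords_mm[peak, ], distances_mm = dmm)
}

# all permutations of 1..n (n <= 8), in lexicographic order
all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive permutations limited to n <= 8")
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out[r + seq_len(nrow(sub)), ] <- cbind(first, matrix(rest[sub],
                                                         nrow(sub)))
    r <- r + nrow(sub)
  }
  out
}

#' Permutation test of the gradient-distance correlation
#'
#' Pearson correlation between gradient values and distances from the peak,
#' with a null built by shuffling the gradient values across voxels and
#' recomputing the correlation.  The p-value is the fraction of null
#' correlations at least as large in magnitude as the observed one
#' (two-sided on |r|); when no null value reaches it, the p-value is
#' reported as `< 1/n_perm`.
#'
#' @param gradient numeric per-voxel gradient values.
#' @param distances numeric per-voxel distances (e.g. from
#'   [distance_from_peak()]).
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed for the shuffles.
#' @param exhaustive if `TRUE`, enumerate all `n!` permutations instead of
#'   sampling (n <= 8).
#' @return An object of class `geometry_test`: `r_observed`, `p_perm`
#'   (numeric, 0 possible), `p_label` (e.g. `"<2e-04"` at the floor),
#'   `n_perm`, `peak_voxel_id`/`distances_mm` when constructed via
#'   [gradient_geometry()].
#' @export
gradient_distance_test <- function(gradient, distances, n_perm = 5000L,
                                   seed = NULL, exhaustive = FALSE) {
  stopifnot(length(gradient) == length(distances), n_perm >= 1L)
  if (stats::sd(gradient) == 0 || stats::sd(distances) == 0)
    stop("zero-variance input: correlation undefined")
  r_obs <- stats::cor(gradient, distances)
  n <- length(gradient)
  if (exhaustive) {
    perms <- t(all_permutations(n))
    n_perm <- ncol(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perms <- replicate(n_perm, sample.int(n))
  }
  G <- matrix(gradient[perms], nrow = n)
  r_null <- as.vector(stats::cor(distances, G))
  hits <- sum(abs(r_null) >= abs(r_obs) - 1e-15)
  p <- hits / n_perm
  structure(
    list(r_observed = r_obs, p_perm = p,
         p_label = if (hits == 0) sprintf("<%g", 1 / n_perm) else
           sprintf("%g", p),
         n_perm = n_perm, exhaustive = exhaustive),
    class = "geometry_test")
}

#' @export
print.geometry_test <- function(x, ...) {
  cat(sprintf(
    "<geometry_test> r = %.4f, p_perm %s (%d permutations%s)\n",
    x$r_observed, if (x$p_perm == 0) x$p_label else sprintf("= %s", x$p_label),
    x$n_perm, if (isTRUE(x$exhaustive)) ", exhaustive" else ""))
  invisible(x)
}

#' Gradient-geometry analysis per hemisphere
#'
#' Convenience wrapper running [distance_from_peak()] and
#' [gradient_distance_test()] on the whole seed or separately per
#' hemisphere.
#'
#' @param gradient per-voxel gradient values (or a `gradient_set`, in which
#'   case its dominant gradient and grid are used).
#' @param grid the [voxel_grid()]; ignored if `gradient` is a `gradient_set`.
#' @param hemisphere `"both"`, `"L"` or `"R"`.
#' @param n_perm,seed passed to [gradient_distance_test()].
#' @return A named list of `geometry_test` objects (one per analyzed
#'   hemisphere), each augmented with `peak_voxel_id`, `peak_mm` and
#'   `hemisphere`.
#' @export
gradient_geometry <- function(gradient, grid = NULL,
                              hemisphere = c("both", "L", "R"),
                              n_perm = 5000L, seed = NULL) {
  if (inherits(gradient, "gradient_set")) {
    grid <- gradient$grid
    gradient <- dominant_gradient(gradient)
  }
  hemisphere <- match.arg(hemisphere)
  sides <- if (hemisphere == "both") c("L", "R") else hemisphere
  sides <- intersect(sides, unique(grid$hemisphere))
  if (length(sides) == 0L) {                 # single-hemisphere grids
    sides <- "all"
    sel <- list(all = rep(TRUE, n_voxels(grid)))
  } else {
    sel <- lapply(sides, function(s) grid$hemisphere == s)
    names(sel) <- sides
  }
  out <- lapply(sides, function(s) {
    g <- gradient[sel[[s]]]
    sub <- grid[sel[[s]]]
    dp <- distance_from_peak(g, sub)
    res <- gradient_distance_test(g, dp$distances_mm, n_perm = n_perm,
                                  seed = seed)
    res$peak_voxel_id <- dp$peak_voxel_id
    res$peak_mm <- dp$peak_mm
    res$distances_mm <- dp$distances_mm
    res$hemisphere <- s
    res
  })
  names(out) <- sides
  out
}
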