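# Meta-analytic term decoding: decile bins of the dominant gradient and
# per-term mean-z profiles along them.

#' Rank-based decile bins of the gradient
#'
#' Voxels are ranked ascending by gradient value (ties broken by voxel id)
#' and split into 10 equal-count bins; bin sizes differ by at most one
#' voxel and the bins partition the seed.  Rank-based (equal-count) binning
#' means duplicated gradient values can never empty a bin.
#'
#' @param gradient per-voxel gradient values (>= 10 voxels).
#' @param n_bins number of bins (default 10).
#' @return Integer per-voxel bin index in 1..n_bins (1 = lowest gradient
#'   decile), with attribute `"edges"` giving the n_bins+1 delimiting
#'   gradient values.
#' @export
bin_gradient <- function(gradient, n_bins = 10L) {
  n <- length(gradient)
  if (n < n_bins)
    stop(sprintf("need at least %d voxels for %d bins", n_bins, n_bins))
  ord <- order(gradient, seq_along(gradient))
  bin_of_rank <- ceiling(seq_len(n) * n_bins / n)
  bins <- integer(n)
  bins[ord] <- bin_of_rank
  sorted <- gradient[ord]
  edges <- c(sorted[1L],
             vapply(seq_len(n_bins - 1L), function(b)
               sorted[max(which(bin_of_rank == b))], numeric(1)),
             sorted[n])
  attr(bins, "edges") <- edges
  bins
}

#' Profile term z-maps along the gradient bins
#'
#' For each term, the mean z-statistic within each gradient decile mask is
#' extracted.  A term is retained when its maximum bin mean exceeds
#' `z_threshold` (strict inequality).  For visualization ordering, each
#' retained term gets a positive-part centre-of-mass statistic across bins:
#' `sum(b * max(profile_b, 0)) / sum(max(profile_b, 0))`.
#'
#' @param bins per-voxel bin index from [bin_gradient()].
#' @param term_maps term x voxel matrix of z values (rownames = term names),
#'   sampled on the seed grid.  NaN/NA voxels are excluded from bin means
#'   with a warning; all-NA terms are dropped.
#' @param z_threshold retention threshold on the max bin mean (default 2.3).
#' @return An object of class `term_decoding`: `profile` (term x n_bins),
#'   `retained` (logical per term), `term_order` (centre of mass, NA for
#'   non-positive profiles), `bin_edges`, `z_threshold`.
#' @export
decode_terms <- function(bins, term_maps, z_threshold = 2.3) {
  term_maps <- as.matrix(term_maps)
  if (ncol(term_maps) != length(bins))
    stop("term maps must be sampled on the seed grid (one column per voxel)")
  if (is.null(rownames(term_maps)))
    rownames(term_maps) <- paste0("term", seq_len(nrow(term_maps)))
  n_bins <- max(bins)
  all_na <- rowSums(!is.na(term_maps)) == 0L
  if (any(all_na)) {
    warning(sprintf("dropping %d all-NA term map(s)", sum(all_na)))
    term_maps <- term_maps[!all_na, , drop = FALSE]
  }
  if (anyNA(term_maps))
    warning("NA voxels in term maps excluded from bin means")
  profile <- vapply(seq_len(n_bins), function(b) {
    rowMeans(term_maps[, bins == b, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(term_maps)))
  profile <- matrix(profile, nrow = nrow(term_maps),
                    dimnames = list(rownames(term_maps), NULL))
  colnames(profile) <- paste0("bin", seq_len(n_bins))
  retained <- apply(profile, 1L, max, na.rm = TRUE) > z_threshold
  pos <- pmax(profile, 0)
  pos[is.na(pos)] <- 0
  denom <- rowSums(pos)
  term_order <- ifelse(denom > 0,
                       as.vector(pos %*% seq_len(n_bins)) / denom, NA_real_)
  names(term_order) <- rownames(profile)
  structure(
    list(profile = profile, retained = retained, term_order = term_order,
         bin_edges = attr(bins, "edges"), z_threshold = z_threshold),
    class = "term_decoding")
}

#' @export
print.term_decoding <- function(x, ...) {
  cat(sprintf("<term_decoding> %d terms, %d retained at z > %g\n",
              nrow(x$profile), sum(x$retained), x$z_threshold))
  if (any(x$retained)) {
    ord <- order(x$term_order[x$retained])
    cat("  retained (by gradient position):",
        paste(rownames(x$profile)[x$retained][ord], collapse = ", "), "\n")
  }
  invisible(x)
}
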