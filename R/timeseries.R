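# Group-level time-series assembly and confound residualization.

# population-sd z-scoring of each row of a voxel x time matrix;
# constant rows become all-zero and are reported via the "constant" attribute
zscore_rows <- function(x, tol = 1e-12) {
  mu <- rowMeans(x)
  xc <- x - mu
  sdp <- sqrt(rowMeans(xc^2))
  const <- sdp <= tol
  sdp[const] <- 1
  out <- xc / sdp
  out[const, ] <- 0
  attr(out, "constant") <- which(const)
  out
}

#' Standardize per-subject BOLD blocks and concatenate them in time
#'
#' Each subject's voxel-by-time block is z-scored per voxel over time
#' (population standard deviation), then the blocks are concatenated along
#' the time axis to give group-level time courses.  Voxels with a constant
#' series within a block are set to all-zero for that block and reported.
#'
#' @param per_subject list of voxel x time matrices, one per subject, all
#'   with the same number of rows.
#' @param grid the [voxel_grid()] describing the rows.
#' @return An object of class `group_timeseries`: `values` (voxel x total
#'   time), `subject_boundaries` (matrix with 0-based half-open `start`,
#'   `end` columns, one row per subject), `grid`, and `constant_voxels`
#'   (0-based ids of voxels flagged constant in any block).
#' @export
standardize_and_concatenate <- function(per_subject, grid) {
  stopifnot(is.list(per_subject), length(per_subject) >= 1L)
  nv <- vapply(per_subject, nrow, integer(1))
  if (length(unique(nv)) != 1L)
    stop(sprintf("subjects disagree on voxel count: %s",
                 paste(unique(nv), collapse = ", ")))
  if (nv[1L] != n_voxels(grid))
    stop("grid voxel count does not match the matrices")
  blocks <- lapply(per_subject, zscore_rows)
  const <- sort(unique(unlist(lapply(blocks, attr, "constant"))))
  if (length(const))
    warning(sprintf("%d voxel(s) had a constant time series and were zeroed",
                    length(const)))
  nt <- vapply(per_subject, ncol, integer(1))
  ends <- cumsum(nt)
  bounds <- cbind(start = c(0L, ends[-length(ends)]), end = ends)
  structure(
    list(values = do.call(cbind, blocks), subject_boundaries = bounds,
         grid = grid, constant_voxels = const - 1L),
    class = "group_timeseries")
}

#' @export
print.group_timeseries <- function(x, ...) {
  cat(sprintf("<group_timeseries> %d voxels x %d timepoints (%d subjects)\n",
              nrow(x$values), ncol(x$values), nrow(x$subject_boundaries)))
  invisible(x)
}

#' Regress confound time series out of voxel time courses
#'
#' Least-squares residualization of each voxel's series against the confound
#' columns plus an intercept (added internally).  Collinear confound columns
#' are dropped with a warning.  Residuals are orthogonal to every retained
#' confound column.
#'
#' @param series voxel x time matrix.
#' @param confounds time x k matrix (k may be 0: intercept-only, i.e.
#'   demeaning).
#' @return voxel x time matrix of residuals.
#' @export
regress_confounds <- function(series, confounds = NULL) {
  series <- as.matrix(series)
  nt <- ncol(series)
  if (is.null(confounds)) confounds <- matrix(0, nt, 0L)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nt)
    stop("confounds must have one row per timepoint")
  X <- cbind(intercept = 1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[(qx$rank + 1L):ncol(X)]
    warning(sprintf("dropping %d collinear confound column(s)", length(drop)))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  t(qr.resid(qx, t(series)))
}
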