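#' Voxel grid: the spatial frame of all maps
#'
#' A `voxel_grid` ties together the ordered voxel indices of a masked region,
#' their MNI-millimetre coordinates (derived from the volume's affine), a
#' per-voxel subregion tag and a hemisphere label.  Every map produced by the
#' package (gradients, distances, parcellations) is ordered by `voxel_ids`,
#' which are 0-based and contiguous, following the mask's native array order
#' (ascending linear index, first array dimension fastest).
#'
#' @param coords_mm numeric matrix, one row per voxel, columns x/y/z in mm.
#' @param region_label character vector of per-voxel subregion tags.
#' @param hemisphere character vector of `"L"`/`"R"` per voxel.  Defaults to
#'   the sign of the x coordinate (negative x = left), the MNI convention.
#' @return An object of class `voxel_grid` with fields `voxel_ids`,
#'   `coords_mm`, `region_label`, `hemisphere`.
#' @export
voxel_grid <- function(coords_mm, region_label = NULL, hemisphere = NULL) {
  coords_mm <- as.matrix(coords_mm)
  if (ncol(coords_mm) != 3L)
    stop("coords_mm must have three columns (x, y, z in mm)")
  if (!all(is.finite(coords_mm)))
    stop("coords_mm must be finite")
  n <- nrow(coords_mm)
  if (is.null(region_label)) region_label <- rep("seed", n)
  if (is.null(hemisphere))
    hemisphere <- ifelse(coords_mm[, 1L] < 0, "L", "R")
  region_label <- as.character(region_label)
  hemisphere <- as.character(hemisphere)
  if (length(region_label) != n || length(hemisphere) != n)
    stop("region_label and hemisphere must have one entry per voxel")
  if (anyNA(region_label))
    stop("every voxel must carry exactly one region_label")
  structure(
    list(voxel_ids = 0:(n - 1L), coords_mm = unname(coords_mm),
         region_label = region_label, hemisphere = hemisphere),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d voxels, %d region label(s), hemispheres: %s\n",
              length(x$voxel_ids), length(unique(x$region_label)),
              paste(names(table(x$hemisphere)), table(x$hemisphere),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' @export
length.voxel_grid <- function(x) length(x$voxel_ids)

#' Subset a voxel grid
#'
#' Keeps the voxels selected by `i` (logical or integer positions into the
#' grid's row order) and renumbers `voxel_ids` contiguously from 0.
#'
#' @param x a `voxel_grid`.
#' @param i logical or integer index into the grid's voxels.
#' @param ... ignored.
#' @export
`[.voxel_grid` <- function(x, i, ...) {
  voxel_grid(x$coords_mm[i, , drop = FALSE], x$region_label[i],
             x$hemisphere[i])
}

n_voxels <- function(grid) length(grid$voxel_ids)
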