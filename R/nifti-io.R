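# NIfTI plumbing.  Volumes are read and written through RNifti; all voxel
# indices used for coordinates are 0-based, and world coordinates are the
# affine applied to 0-based indices (NIfTI convention).

#' Write a 3D or 4D array as a NIfTI volume with an explicit affine
#'
#' @param data numeric array (3D or 4D).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world matrix (applied to 0-based indices).
#' @param datatype storage datatype, default `"double"` so round-trips are
#'   bitwise exact.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, affine = diag(4), datatype = "double") {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  pd <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(data, reference = list(
    pixdim = c(1, pd, rep(1, 4)),
    sform_code = 2L,
    srow_x = affine[1L, ], srow_y = affine[2L, ], srow_z = affine[3L, ]))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read the voxel-to-world affine of a NIfTI image
#' @param image an RNifti image or a path.
#' @return 4x4 numeric matrix.
#' @export
volume_affine <- function(image) {
  if (is.character(image)) image <- RNifti::readNifti(image)
  m <- RNifti::xform(image)
  attributes(m) <- list(dim = dim(m))
  m
}

# world coordinates of 0-based voxel indices (n x 3 integer matrix)
ijk_to_mm <- function(ijk0, affine) {
  ijk0 <- matrix(as.numeric(ijk0), ncol = 3L)
  sweep(ijk0 %*% t(affine[1:3, 1:3]), 2L, affine[1:3, 4L], `+`)
}

#' Extract masked voxel time series from a 4D BOLD volume
#'
#' Reads a 4D BOLD volume and a 3D binary mask sharing its grid, and returns
#' the voxel-by-time matrix of the masked voxels together with the
#' `voxel_grid` describing them.  Rows are ordered by ascending linear voxel
#' index in the mask's native array order; all downstream maps inherit this
#' order.
#'
#' @param volume_path path to the 4D NIfTI BOLD volume.
#' @param mask_path path to the 3D binary NIfTI mask.
#' @param region_volume optional path to a 3D integer label volume on the
#'   same grid; nonzero labels become per-voxel `region_label`s
#'   (`"region<k>"`), zero falls back to `"seed"`.
#' @return A list with `values` (voxel x time matrix) and `grid`
#'   (a [voxel_grid()]).
#' @export
load_masked_bold <- function(volume_path, mask_path, region_volume = NULL) {
  vol <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  dv <- dim(vol); dm <- dim(msk)
  if (length(dv) != 4L)
    stop(sprintf("'%s' is not a 4D volume", volume_path))
  if (length(dm) != 3L || !all(dv[1:3] == dm))
    stop(sprintf("shape mismatch between '%s' (%s) and mask '%s' (%s)",
                 volume_path, paste(dv, collapse = "x"),
                 mask_path, paste(dm, collapse = "x")))
  av <- volume_affine(vol); am <- volume_affine(msk)
  if (max(abs(av - am)) > 1e-4)
    stop(sprintf("affine mismatch between '%s' and mask '%s'",
                 volume_path, mask_path))
  mvals <- as.vector(msk)
  if (!all(mvals %in% c(0, 1)))
    stop(sprintf("mask '%s' is not binary", mask_path))
  idx <- which(mvals != 0)
  if (length(idx) == 0L)
    stop(sprintf("mask '%s' is empty", mask_path))
  nt <- dv[4L]
  mat <- matrix(as.vector(vol), nrow = prod(dv[1:3]), ncol = nt)[idx, ,
                                                                 drop = FALSE]
  ijk0 <- arrayInd(idx, dm) - 1L
  coords <- ijk_to_mm(ijk0, av)
  labels <- NULL
  if (!is.null(region_volume)) {
    reg <- RNifti::readNifti(region_volume)
    if (!all(dim(reg) == dm))
      stop(sprintf("shape mismatch between region volume '%s' and mask '%s'",
                   region_volume, mask_path))
    rv <- as.vector(reg)[idx]
    labels <- ifelse(rv != 0, paste0("region", as.integer(rv)), "seed")
  }
  list(values = mat, grid = voxel_grid(coords, region_label = labels))
}

#' Write per-voxel values of a grid back into volume space
#'
#' Places a per-voxel statistic (e.g. the dominant gradient) into a 3D volume
#' whose masked voxels are those of `grid`, and writes it as NIfTI.
#'
#' @param values numeric vector, one value per grid voxel.
#' @param grid the `voxel_grid` of the values.
#' @param dim3 integer length-3 array dimensions of the target volume.
#' @param mask_index 1-based linear indices of the grid's voxels in the
#'   volume, in grid order.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output path.
#' @param background fill value outside the mask (default 0).
#' @export
write_voxel_map <- function(values, grid, dim3, mask_index, affine, path,
                            background = 0) {
  stopifnot(length(values) == n_voxels(grid),
            length(mask_index) == n_voxels(grid))
  arr <- array(background, dim = dim3)
  arr[mask_index] <- values
  write_volume(arr, path, affine)
}
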