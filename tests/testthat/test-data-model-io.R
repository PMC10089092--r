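test_that("masked BOLD extraction keeps shape, order and affine coordinates", {
  dir <- withr::local_tempdir()
  set.seed(5)
  vol <- array(rnorm(4 * 4 * 4 * 10), c(4, 4, 4, 10))
  mask <- array(0, c(4, 4, 4))
  vox <- rbind(c(1, 1, 1), c(2, 3, 4), c(3, 1, 2), c(4, 4, 1), c(2, 2, 2))
  mask[vox] <- 1
  aff <- diag(c(3, 3, 3, 1))
  vp <- file.path(dir, "bold.nii.gz"); mp <- file.path(dir, "mask.nii.gz")
  write_volume(vol, vp, aff)
  write_volume(mask, mp, aff)

  got <- load_masked_bold(vp, mp)
  expect_equal(dim(got$values), c(5L, 10L))
  expect_equal(nrow(got$grid$coords_mm), 5L)
  # rows in ascending linear index order, values bitwise equal to the source
  idx <- which(as.vector(mask) != 0)
  flat <- matrix(as.vector(vol), nrow = 64)
  expect_identical(got$values, flat[idx, ])
  # affine = 3 * identity, zero origin: voxel (1,2,3) 0-based -> (3,6,9) mm
  mask2 <- array(0, c(4, 4, 4)); mask2[2, 3, 4] <- 1
  mp2 <- file.path(dir, "mask2.nii.gz")
  write_volume(mask2, mp2, aff)
  got2 <- load_masked_bold(vp, mp2)
  expect_equal(as.vector(got2$grid$coords_mm), c(3, 6, 9))
})

test_that("masked BOLD extraction rejects bad inputs by name", {
  dir <- withr::local_tempdir()
  vol <- array(0, c(4, 4, 4, 3))
  vp <- file.path(dir, "b.nii.gz")
  write_volume(vol, vp, diag(4))
  bad <- file.path(dir, "m.nii.gz")
  write_volume(array(0, c(3, 3, 3)), bad, diag(4))
  expect_error(load_masked_bold(vp, bad), "shape mismatch.*m\\.nii")
  empty <- file.path(dir, "e.nii.gz")
  write_volume(array(0, c(4, 4, 4)), empty, diag(4))
  expect_error(load_masked_bold(vp, empty), "empty")
  shifted <- file.path(dir, "s.nii.gz")
  m <- array(0, c(4, 4, 4)); m[1, 1, 1] <- 1
  write_volume(m, shifted, diag(c(2, 2, 2, 1)))
  expect_error(load_masked_bold(vp, shifted), "affine mismatch")
})

test_that("per-subject z-scoring uses the population sd and records blocks", {
  grid <- voxel_grid(matrix(seq_len(3 * 3), 3, 3))
  one <- matrix(c(1, 2, 3), 1, 3)
  gt <- standardize_and_concatenate(list(rbind(one, one, one)), grid[1:3])
  expect_equal(gt$values[1, ], c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  s1 <- matrix(rnorm(300), 3, 100); s2 <- matrix(rnorm(360), 3, 120)
  gt2 <- standardize_and_concatenate(list(s1, s2), grid)
  expect_equal(ncol(gt2$values), 220L)
  expect_equal(unname(gt2$subject_boundaries),
               cbind(c(0L, 100L), c(100L, 220L)))
  # within each block every row has mean 0, population variance 1
  for (b in seq_len(2)) {
    blk <- gt2$values[, (gt2$subject_boundaries[b, 1] + 1):
                        gt2$subject_boundaries[b, 2]]
    expect_lt(max(abs(rowMeans(blk))), 1e-8)
    expect_lt(max(abs(rowMeans(blk^2) - 1)), 1e-8)
  }

  const <- rbind(matrix(rnorm(20), 2, 10), 7)
  expect_warning(gt3 <- standardize_and_concatenate(list(const), grid),
                 "constant")
  expect_equal(gt3$values[3, ], rep(0, 10))
  expect_equal(gt3$constant_voxels, 2L)

  expect_error(standardize_and_concatenate(list(s1, matrix(0, 2, 5)), grid),
               "voxel count")
})

test_that("z-scoring is idempotent per block", {
  set.seed(8)
  grid <- voxel_grid(matrix(rnorm(12), 4, 3))
  x <- matrix(rnorm(160), 4, 40)
  once <- standardize_and_concatenate(list(x), grid)
  twice <- standardize_and_concatenate(list(once$values), grid)
  expect_lt(max(abs(once$values - twice$values)), 1e-10)
})

test_that("confound regression removes confounds and nothing else", {
  set.seed(13)
  x <- matrix(rnorm(5 * 60), 5, 60)
  # self-regression annihilates the series
  res <- regress_confounds(x[1, , drop = FALSE], cbind(x[1, ]))
  expect_lt(max(abs(res)), 1e-10)
  # intercept-only equals demeaning
  res2 <- regress_confounds(x, NULL)
  expect_equal(res2, x - rowMeans(x), tolerance = 1e-12)
  # constructed decomposition: orthogonal signal survives exactly
  conf <- rnorm(60)
  signal <- qr.resid(qr(cbind(1, conf)), rnorm(60))
  series <- rbind(signal + 2 * conf)
  res3 <- regress_confounds(series, cbind(conf))
  expect_lt(max(abs(res3 - rbind(signal))), 1e-8)
  # residuals orthogonal to each confound column
  cf <- cbind(rnorm(60), rnorm(60))
  res4 <- regress_confounds(x, cf)
  orth <- crossprod(t(res4), scale(cf))
  expect_lt(max(abs(orth)) / 60, 1e-6)
  # collinear confounds dropped with a warning
  expect_warning(regress_confounds(x, cbind(conf, 2 * conf)), "collinear")
})

test_that("orthonormal confound regression equals projection subtraction", {
  set.seed(21)
  x <- matrix(rnorm(3 * 50), 3, 50)
  q <- qr.Q(qr(cbind(1, rnorm(50), rnorm(50))))[, 2:3]  # orthonormal, centred
  res <- regress_confounds(x, q)
  proj <- function(v) v - mean(v) - q %*% crossprod(q, v - mean(v))
  manual <- t(apply(x, 1, proj))
  expect_equal(res, manual, tolerance = 1e-10)
})

test_that("expression panels and annotation sets round-trip through disk", {
  dir <- withr::local_tempdir()
  set.seed(3)
  panel <- expression_panel(matrix(rnorm(5 * 8), 5, 8,
                                   dimnames = list(NULL, paste0("G", 1:8))),
                            matrix(rnorm(15), 5, 3))
  p <- file.path(dir, "panel.tsv")
  write_expression_panel(panel, p)
  back <- read_expression_panel(p)
  expect_equal(back$expression, panel$expression, tolerance = 1e-12)
  expect_equal(back$sample_coords_mm, panel$sample_coords_mm,
               tolerance = 1e-12)
  expect_identical(back$gene_symbols, panel$gene_symbols)

  sets <- list(alpha = c("G1", "G2"), beta = c("G3", "G4", "G5"))
  gp <- file.path(dir, "sets.gmt")
  write_annotation_sets(sets, gp)
  expect_identical(read_annotation_sets(gp), sets)
  # comma-list dialect without a description column
  writeLines(c("one\tG1,G2", "two\tG9"), gp)
  expect_identical(read_annotation_sets(gp),
                   list(one = c("G1", "G2"), two = "G9"))
})

test_that("volume round-trips are bitwise at stored dtype", {
  dir <- withr::local_tempdir()
  set.seed(4)
  a <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  p <- file.path(dir, "v.nii.gz")
  write_volume(a, p, diag(c(3, 3, 3, 1)))
  back <- RNifti::readNifti(p)
  expect_identical(array(as.numeric(back), dim(back)), a)
})
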