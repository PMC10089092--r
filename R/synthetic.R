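# Synthetic-data generator with planted ground truth.
#
# The world plants one latent hierarchy axis in [0, 1].  Every voxel (seed
# and target) carries a latent position; K = 7 network source signals sit at
# fixed latent centres, and a voxel's BOLD series is the Gaussian-coupled
# mixture of the sources plus white noise:
#   series_v = sum_k exp(-(latent_v - centre_k)^2 / (2 sigma_c^2)) source_k
#              + sigma_n * noise.
# Connectivity between two voxels therefore decays smoothly with their
# latent separation, so the dominant diffusion gradient of the seed should
# recover the planted axis.  The seed latent runs along the y (anterior-
# posterior) spatial axis, mirrored in both hemispheres; target voxels carry
# network labels grouped by latent centre with a DMN-like network at one
# extreme and visual/sensorimotor-like networks at the other.

SYNTH_NETWORKS <- c("visual", "sensorimotor", "DAN", "VAN", "limbic",
                    "FPN", "DMN")
SYNTH_CENTERS <- c(visual = 0.05, sensorimotor = 0.20, DAN = 0.35,
                   VAN = 0.50, limbic = 0.65, FPN = 0.80, DMN = 0.95)

# per-hemisphere seed block: 2 x-columns, 2 z-slices, latent along y
seed_layout <- function(n_seed) {
  stopifnot(n_seed %% 2L == 0L, n_seed >= 16L)
  nh <- n_seed %/% 2L
  ny <- ceiling(nh / 4)
  list(nh = nh, ny = ny)
}

gaussian_weights <- function(latent, centers, width) {
  outer(latent, centers, function(l, c) exp(-(l - c)^2 / (2 * width^2)))
}

#' Generate a synthetic connectivity world with a planted latent axis
#'
#' See the package vignette for the generative model.  All randomness is a
#' pure function of `seed`.
#'
#' @param n_seed number of seed voxels (even, >= 16; default 200, i.e. 100
#'   per hemisphere).
#' @param n_target number of labeled target voxels (default 1000).
#' @param n_time timepoints per subject (>= 50; default 200).
#' @param n_subjects subjects to concatenate (default 3).
#' @param coupling_width Gaussian coupling width sigma_c on the latent axis
#'   (default 0.1).
#' @param noise_sd white-noise standard deviation sigma_n relative to
#'   unit-variance sources (default 1.0, i.e. SNR 1).
#' @param seed master RNG seed (default 42).
#' @return An object of class `synthetic_world`: `per_subject_seed` /
#'   `per_subject_target` (lists of voxel x time matrices), `seed_grid`,
#'   `target_grid`, `network_labels` (per target voxel), `truth` (latents,
#'   labels, centres, child seeds), and volume metadata (`dim3`, `affine`,
#'   `seed_mask_index`, `target_mask_index`) for writing NIfTI files.
#' @export
make_connectivity_world <- function(n_seed = 200L, n_target = 1000L,
                                    n_time = 200L, n_subjects = 3L,
                                    coupling_width = 0.1, noise_sd = 1.0,
                                    seed = 42L) {
  if (n_time < 50L) stop("n_time must be >= 50")
  if (coupling_width <= 0 || noise_sd < 0)
    stop("coupling_width must be positive and noise_sd non-negative")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, 3L)

  lay <- seed_layout(n_seed)
  nh <- lay$nh; ny <- lay$ny
  ny_t <- ceiling(n_target / 40)
  dim3 <- c(14L, max(ny, ny_t), 8L)
  affine <- rbind(c(3, 0, 0, -21), c(0, 3, 0, -3 * (dim3[2] + 1) / 2),
                  c(0, 0, 3, -6), c(0, 0, 0, 1))

  # seed voxels: enumerate (y, z, x) per hemisphere; latent = rank / (nh-1)
  hemi_block <- function(x_cols) {
    g <- expand.grid(x = x_cols, z = 1:2, y = seq_len(ny))
    g <- g[order(g$y, g$z, g$x), ][seq_len(nh), ]
    # y-dominated latent with small within-slab increments, so the latent
    # is essentially the y axis (|r| >= 0.99) but still voxel-unique
    r <- seq_len(nh) - 1L
    raw <- (r %/% 4L) + 0.2 * ((r %% 4L) / 3 - 0.5)
    g$latent <- (raw - min(raw)) / (max(raw) - min(raw))
    g
  }
  seed_tab <- rbind(cbind(hemi_block(1:2), hemi = "L"),
                    cbind(hemi_block(13:14), hemi = "R"))
  # target voxels in a separate block, networks in contiguous latent-ordered
  # chunks with jittered latents around each network's centre
  tg <- expand.grid(x = 3:12, z = 5:8, y = seq_len(ny_t))
  tg <- tg[order(tg$y, tg$z, tg$x), ][seq_len(n_target), ]
  net_id <- ceiling(seq_len(n_target) * length(SYNTH_NETWORKS) / n_target)
  set.seed(child[1L])
  tg$latent <- pmin(pmax(
    SYNTH_CENTERS[net_id] + stats::runif(n_target, -0.07, 0.07), 0), 1)

  # reorder both blocks to the mask's native linear-index order, so that
  # load_masked_bold() on the written volumes reproduces the same rows
  lin <- function(tab) tab$x + (tab$y - 1L) * dim3[1L] +
    (tab$z - 1L) * dim3[1L] * dim3[2L]
  seed_tab$net <- NA
  seed_ord <- order(lin(seed_tab))
  seed_tab <- seed_tab[seed_ord, ]
  tg$net <- SYNTH_NETWORKS[net_id]
  tg_ord <- order(lin(tg))
  tg <- tg[tg_ord, ]

  mm <- function(tab) ijk_to_mm(cbind(tab$x, tab$y, tab$z) - 1L, affine)
  # synthetic seed-subregion tags along the latent axis (terciles)
  subregion <- c("A39rv", "A39rd", "A39c")[pmin(
    floor(seed_tab$latent * 3) + 1L, 3L)]
  seed_grid <- voxel_grid(mm(seed_tab), region_label = subregion,
                          hemisphere = seed_tab$hemi)
  target_grid <- voxel_grid(mm(tg), region_label = tg$net)

  Ws <- gaussian_weights(seed_tab$latent, SYNTH_CENTERS, coupling_width)
  Wt <- gaussian_weights(tg$latent, SYNTH_CENTERS, coupling_width)
  K <- length(SYNTH_CENTERS)
  set.seed(child[2L])
  per_seed <- vector("list", n_subjects)
  per_target <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    src <- matrix(stats::rnorm(K * n_time), K, n_time)
    per_seed[[s]] <- Ws %*% src +
      noise_sd * matrix(stats::rnorm(n_seed * n_time), n_seed)
    per_target[[s]] <- Wt %*% src +
      noise_sd * matrix(stats::rnorm(n_target * n_time), n_target)
  }
  truth <- structure(
    list(latent = seed_tab$latent, target_latent = tg$latent,
         network_labels = tg$net, network_centers = SYNTH_CENTERS,
         tracking_genes = NULL, term_peaks = NULL,
         seeds = c(master = seed, targets = child[1L], bold = child[2L],
                   spare = child[3L])),
    class = "synthetic_truth")
  structure(
    list(per_subject_seed = per_seed, per_subject_target = per_target,
         seed_grid = seed_grid, target_grid = target_grid,
         network_labels = tg$net, truth = truth,
         dim3 = dim3, affine = affine,
         seed_mask_index = lin(seed_tab), target_mask_index = lin(tg),
         n_time = n_time, n_subjects = n_subjects,
         coupling_width = coupling_width, noise_sd = noise_sd),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d seed + %d target voxels, %d subjects x %d t\n",
    n_voxels(x$seed_grid), n_voxels(x$target_grid), x$n_subjects, x$n_time))
  invisible(x)
}

#' Planted latent expected winner-take-all assignment of seed voxels
#'
#' The network whose latent centre is nearest each seed voxel's planted
#' latent position: the ground truth for parcellation recovery.
#'
#' @param world a `synthetic_world`.
#' @return Character vector of network names per seed voxel.
#' @export
planted_assignment <- function(world) {
  centers <- world$truth$network_centers
  names(centers)[apply(
    abs(outer(world$truth$latent, centers, `-`)), 1L, which.min)]
}

#' Generate a synthetic tissue-sample expression panel tracking the latent
#'
#' Samples sit at the coordinates of randomly chosen seed voxels.  A planted
#' fraction of genes tracks the latent axis,
#' `expr = +/- beta * z(latent) + sigma * noise` (half with each sign),
#' where `z(latent)` is the latent standardized across the drawn samples so
#' that `beta` is a standardized effect size in noise-sd units; the rest of
#' the genes are pure noise of the same scale.
#'
#' @param world a `synthetic_world`.
#' @param n_samples tissue samples (default 25).
#' @param n_genes genes (default 600).
#' @param frac_tracking fraction of latent-tracking genes in (0, 1)
#'   (default 0.1).
#' @param beta tracking effect size (default 1).
#' @param sigma noise standard deviation (default 0.5).
#' @param seed RNG seed (default 7).
#' @return A list: `panel` (an [expression_panel()]), `tracking_genes`
#'   (data.frame gene/beta; positive beta first), `sample_voxels` (1-based
#'   seed-voxel rows used), `sample_latent`.
#' @export
make_expression_panel <- function(world, n_samples = 25L, n_genes = 600L,
                                  frac_tracking = 0.1, beta = 1,
                                  sigma = 0.5, seed = 7L) {
  if (!(frac_tracking > 0 && frac_tracking < 1))
    stop("frac_tracking must be in (0, 1)")
  set.seed(seed)
  vox <- sample.int(n_voxels(world$seed_grid), n_samples)
  latent <- world$truth$latent[vox]
  genes <- sprintf("G%04d", seq_len(n_genes))
  n_track <- max(2L, round(frac_tracking * n_genes))
  n_track <- n_track + n_track %% 2L        # even: half +beta, half -beta
  betas <- c(rep(beta, n_track / 2), rep(-beta, n_track / 2))
  expr <- matrix(sigma * stats::rnorm(n_samples * n_genes), n_samples,
                 n_genes, dimnames = list(NULL, genes))
  latent_std <- (latent - mean(latent)) / stats::sd(latent)
  expr[, seq_len(n_track)] <- expr[, seq_len(n_track)] +
    outer(latent_std, betas)
  panel <- expression_panel(expr, world$seed_grid$coords_mm[vox, ,
                                                            drop = FALSE])
  list(panel = panel,
       tracking_genes = data.frame(gene = genes[seq_len(n_track)],
                                   beta = betas),
       sample_voxels = vox, sample_latent = latent)
}

#' Generate meta-analytic style term z-maps peaking along the latent axis
#'
#' Term t's per-seed-voxel z value is
#' `amplitude_t * exp(-(latent - peak_t)^2 / (2 peak_width^2)) + noise`.
#'
#' @param world a `synthetic_world`.
#' @param n_terms number of terms (default 12); peaks are equally spaced on
#'   [0, 1].
#' @param peak_width Gaussian width on the latent axis (default 0.1, i.e. about
#'   one decile bin).
#' @param amplitude peak z amplitude, scalar or per-term (default 5).
#' @param noise_sd additive noise sd (default 0.1).
#' @param seed RNG seed (default 13).
#' @return A list: `maps` (term x seed-voxel z matrix), `peaks` (planted
#'   latent peak positions, named by term).
#' @export
make_term_maps <- function(world, n_terms = 12L, peak_width = 0.1,
                           amplitude = 5, noise_sd = 0.1, seed = 13L) {
  set.seed(seed)
  peaks <- seq(0, 1, length.out = n_terms)
  amplitude <- rep_len(amplitude, n_terms)
  latent <- world$truth$latent
  maps <- t(vapply(seq_len(n_terms), function(t) {
    amplitude[t] * exp(-(latent - peaks[t])^2 / (2 * peak_width^2)) +
      noise_sd * stats::rnorm(length(latent))
  }, numeric(length(latent))))
  rownames(maps) <- sprintf("term%02d", seq_len(n_terms))
  names(peaks) <- rownames(maps)
  list(maps = maps, peaks = peaks)
}

#' Generate annotation gene sets with one planted enriched set
#'
#' The planted set draws `planted_overlap_frac` of its members from the
#' positive-tracking genes (those with +beta), the rest from background;
#' all other sets are drawn uniformly from the whole panel.
#'
#' @param panel_genes all gene symbols of the panel.
#' @param tracking_plus gene symbols of the positive-tracking genes.
#' @param n_sets total number of sets (default 20).
#' @param set_size genes per set (default 40).
#' @param planted_overlap_frac fraction of the planted set drawn from
#'   tracking genes (default 0.5).
#' @param seed RNG seed (default 29).
#' @return A list: `sets` (named list, GMT-serializable), `planted` (the
#'   planted set's name).
#' @export
make_annotation_sets <- function(panel_genes, tracking_plus, n_sets = 20L,
                                 set_size = 40L,
                                 planted_overlap_frac = 0.5, seed = 29L) {
  set.seed(seed)
  k_plant <- round(planted_overlap_frac * set_size)
  k_plant <- min(k_plant, length(tracking_plus))
  background <- setdiff(panel_genes, tracking_plus)
  planted <- c(sample(tracking_plus, k_plant),
               sample(background, set_size - k_plant))
  sets <- list(planted_set = planted)
  for (i in seq_len(n_sets - 1L))
    sets[[sprintf("random_set%02d", i)]] <- sample(panel_genes, set_size)
  list(sets = sets, planted = "planted_set")
}
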