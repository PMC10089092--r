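# End-to-end orchestration: run configuration, stage chaining, manifest
# writing, synthetic-world serialization and the one-command demo.

#' Default run configuration
#'
#' Analysis defaults: retain the top 10% of connections per row, diffusion
#' anisotropy alpha = 0.5, 10 retained components, 5000 permutations for
#' both permutation tests, 3 mm sample spheres, term retention threshold
#' z > 2.3, top-25% gene selection, q <= 0.05 enrichment significance.
#'
#' @param ... overrides of any configuration field (input paths `bold`,
#'   `seed_mask`, `target_mask`, `networks`, `network_names`, `terms`,
#'   `expression`, `annotations`; output directory `out_dir`; parameters
#'   `retain_fraction`, `alpha`, `n_components`, `n_perm_geometry`,
#'   `n_perm_pls`, `radius_mm`, `z_threshold`, `top_fraction`,
#'   `q_threshold`, `master_seed`, `gsr`, `hemisphere`).
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    bold = NULL, seed_mask = NULL, target_mask = NULL,
    networks = NULL, network_names = NULL, terms = NULL,
    expression = NULL, annotations = NULL, out_dir = NULL,
    retain_fraction = 0.10, alpha = 0.5, n_components = 10L,
    n_perm_geometry = 5000L, n_perm_pls = 5000L, radius_mm = 3,
    z_threshold = 2.3, top_fraction = 0.25, q_threshold = 0.05,
    master_seed = 42L, gsr = FALSE, hemisphere = "both")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration field(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; fields as in [default_run_config()].  Relative
#'   input paths are resolved against the YAML file's directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  pathfields <- c("seed_mask", "target_mask", "networks", "terms",
                  "expression", "annotations")
  resolve <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  for (f in intersect(pathfields, names(y))) y[[f]] <- resolve(y[[f]])
  if (!is.null(y$bold)) y$bold <- resolve(unlist(y$bold))
  do.call(default_run_config, y)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$bold) || is.null(cfg$seed_mask) ||
      is.null(cfg$target_mask))
    stop("config must provide bold, seed_mask and target_mask paths")
  with(cfg, {
    stopifnot(retain_fraction > 0, retain_fraction < 1,
              alpha >= 0, alpha <= 1, n_components >= 1,
              n_perm_geometry >= 1, n_perm_pls >= 1, radius_mm > 0,
              top_fraction > 0, top_fraction < 1,
              hemisphere %in% c("both", "L", "R"))
  })
  invisible(cfg)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes gradient calculation, geometry, network parcellation, term
#' decoding, transcriptome association and enrichment, skipping any stage
#' whose inputs are absent from the configuration, and writes per-stage TSV
#' or NIfTI outputs plus a `manifest.json` (configuration, seeds, and an
#' md5 checksum of every output file) into `cfg$out_dir`.
#'
#' @param cfg a `run_config` (see [default_run_config()] /
#'   [read_run_config()]).
#' @return Invisibly, a list of the stage results (`gradients`, `geometry`,
#'   `parcellation`, `decoding`, `pls`, `enrichment`) plus
#'   `manifest_path`.
#' @export
run_all <- function(cfg) {
  validate_config(cfg)
  out <- cfg$out_dir
  if (is.null(out)) stop("config must set out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  results <- list()

  loaded <- run_stage("load", {
    seed_runs <- lapply(cfg$bold, load_masked_bold, mask_path = cfg$seed_mask)
    target_runs <- lapply(cfg$bold, load_masked_bold,
                          mask_path = cfg$target_mask)
    if (isTRUE(cfg$gsr)) {
      for (s in seq_along(seed_runs)) {
        gs <- colMeans(rbind(seed_runs[[s]]$values, target_runs[[s]]$values))
        seed_runs[[s]]$values <- regress_confounds(seed_runs[[s]]$values,
                                                   cbind(gs))
        target_runs[[s]]$values <- regress_confounds(
          target_runs[[s]]$values, cbind(gs))
      }
    }
    list(seed = standardize_and_concatenate(lapply(seed_runs, `[[`,
                                                   "values"),
                                            seed_runs[[1L]]$grid),
         targets = standardize_and_concatenate(lapply(target_runs, `[[`,
                                                      "values"),
                                               target_runs[[1L]]$grid))
  })

  g <- run_stage("gradient", {
    g <- run_gradient_pipeline(loaded$seed, loaded$targets,
                               retain_fraction = cfg$retain_fraction,
                               alpha = cfg$alpha,
                               n_components = cfg$n_components)
    msk <- RNifti::readNifti(cfg$seed_mask)
    files <- c(files, write_voxel_map(
      dominant_gradient(g), g$grid, dim(msk), which(as.vector(msk) != 0),
      volume_affine(msk), file.path(out, "gradient_1.nii.gz")))
    files <- c(files, write_tsv(summary(g),
                                 file.path(out, "eigenvalues.tsv")))
    g
  })
  results$gradients <- g

  results$geometry <- run_stage("geometry", {
    geo <- gradient_geometry(g, hemisphere = cfg$hemisphere,
                             n_perm = cfg$n_perm_geometry,
                             seed = cfg$master_seed + 1L)
    tab <- do.call(rbind, lapply(geo, function(h) data.frame(
      hemisphere = h$hemisphere, peak_voxel_id = h$peak_voxel_id,
      peak_x = h$peak_mm[1L], peak_y = h$peak_mm[2L],
      peak_z = h$peak_mm[3L], r = h$r_observed, p_perm = h$p_label,
      n_perm = h$n_perm)))
    files <- c(files, write_tsv(tab, file.path(out, "geometry.tsv")))
    geo
  })

  if (!is.null(cfg$networks)) {
    results$parcellation <- run_stage("parcellation", {
      lab <- RNifti::readNifti(cfg$networks)
      msk <- RNifti::readNifti(cfg$target_mask)
      lv <- as.integer(as.vector(lab)[as.vector(msk) != 0])
      nm <- cfg$network_names
      if (is.null(nm)) nm <- paste0("network", sort(unique(lv)))
      labels <- factor(nm[match(lv, sort(unique(lv)))], levels = nm)
      means <- network_mean_timecourses(loaded$targets, labels)
      wta <- winner_take_all(loaded$seed, means, dominant_gradient(g))
      files <- c(files, write_tsv(wta$subdivision_summary,
                                   file.path(out, "subdivisions.tsv")))
      wta
    })
  }

  if (!is.null(cfg$terms)) {
    results$decoding <- run_stage("decoding", {
      tm <- as.matrix(utils::read.delim(cfg$terms, row.names = 1L,
                                        check.names = FALSE))
      bins <- bin_gradient(dominant_gradient(g))
      dec <- decode_terms(bins, tm, z_threshold = cfg$z_threshold)
      tab <- data.frame(term = rownames(dec$profile),
                        retained = dec$retained,
                        term_order = dec$term_order, dec$profile,
                        check.names = FALSE)
      files <- c(files, write_tsv(tab, file.path(out, "term_profile.tsv")))
      dec
    })
  }

  if (!is.null(cfg$expression)) {
    results$pls <- run_stage("transcriptome", {
      panel <- read_expression_panel(cfg$expression)
      pls <- pls_gradient_association(
        panel, g, radius_mm = cfg$radius_mm, n_perm = cfg$n_perm_pls,
        seed = cfg$master_seed + 2L, top_fraction = cfg$top_fraction)
      files <- c(files, write_tsv(
        data.frame(r = pls$r_scores_gradient, p_perm = pls$p_label,
                   n_perm = pls$n_perm, n_samples = pls$n_samples),
        file.path(out, "pls_report.tsv")))
      files <- c(files, write_tsv(summary(pls),
                                   file.path(out, "gene_loadings.tsv")))
      pls
    })

    if (!is.null(cfg$annotations)) {
      results$enrichment <- run_stage("enrichment", {
        sets <- read_annotation_sets(cfg$annotations)
        bg <- results$pls$weights
        enr <- list(
          pls_plus = fisher_enrichment(results$pls$pls_plus, sets,
                                       names(bg), cfg$q_threshold),
          pls_minus = fisher_enrichment(results$pls$pls_minus, sets,
                                        names(bg), cfg$q_threshold))
        files <- c(files,
                    write_tsv(enr$pls_plus,
                              file.path(out, "enrichment_plsplus.tsv")),
                    write_tsv(enr$pls_minus,
                              file.path(out, "enrichment_plsminus.tsv")))
        enr
      })
    }
  }

  manifest <- list(
    config = cfg[order(names(cfg))],
    seeds = list(master = cfg$master_seed,
                 geometry = cfg$master_seed + 1L,
                 pls = cfg$master_seed + 2L),
    outputs = as.list(unname(tools::md5sum(files))) |>
      stats::setNames(basename(files)))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  results$manifest_path <- manifest_path
  invisible(results)
}

#' Write a synthetic world (plus optional panel/terms/sets) to disk
#'
#' Serializes BOLD runs, masks and the network label volume as NIfTI, the
#' expression panel as TSV, term maps as a term x voxel TSV, annotation
#' sets as GMT, the planted truth as JSON, and a ready-to-run `run.yaml`.
#'
#' @param world a [make_connectivity_world()] result.
#' @param dir output directory (created).
#' @param panel optional [make_expression_panel()] result.
#' @param terms optional [make_term_maps()] result.
#' @param sets optional [make_annotation_sets()] result.
#' @return The config read back from the written `run.yaml`.
#' @export
write_world <- function(world, dir, panel = NULL, terms = NULL,
                        sets = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d3 <- world$dim3
  mask_vol <- function(idx) {
    a <- array(0, d3); a[idx] <- 1; a
  }
  write_volume(mask_vol(world$seed_mask_index),
               file.path(dir, "seed_mask.nii.gz"), world$affine)
  write_volume(mask_vol(world$target_mask_index),
               file.path(dir, "target_mask.nii.gz"), world$affine)
  lab <- array(0, d3)
  lab[world$target_mask_index] <- match(world$network_labels,
                                        SYNTH_NETWORKS)
  write_volume(lab, file.path(dir, "networks.nii.gz"), world$affine)
  bold_paths <- character(world$n_subjects)
  for (s in seq_len(world$n_subjects)) {
    vol <- array(0, c(d3, world$n_time))
    step <- prod(d3)
    offs <- (seq_len(world$n_time) - 1L) * step
    vol[as.vector(outer(world$seed_mask_index, offs, `+`))] <-
      as.vector(world$per_subject_seed[[s]])
    vol[as.vector(outer(world$target_mask_index, offs, `+`))] <-
      as.vector(world$per_subject_target[[s]])
    bold_paths[s] <- file.path(dir, sprintf("bold_sub-%02d.nii.gz", s))
    write_volume(vol, bold_paths[s], world$affine)
  }
  cfg <- list(bold = basename(bold_paths), seed_mask = "seed_mask.nii.gz",
              target_mask = "target_mask.nii.gz",
              networks = "networks.nii.gz",
              network_names = SYNTH_NETWORKS)
  if (!is.null(panel)) {
    write_expression_panel(panel$panel, file.path(dir, "expression.tsv"))
    cfg$expression <- "expression.tsv"
  }
  if (!is.null(terms)) {
    tab <- data.frame(term = rownames(terms$maps), terms$maps,
                      check.names = FALSE)
    names(tab)[-1L] <- paste0("v", seq_len(ncol(terms$maps)) - 1L)
    write_tsv(tab, file.path(dir, "terms.tsv"))
    cfg$terms <- "terms.tsv"
  }
  if (!is.null(sets)) {
    write_annotation_sets(sets$sets, file.path(dir, "annotations.gmt"))
    cfg$annotations <- "annotations.gmt"
  }
  truth <- world$truth
  jsonlite::write_json(
    list(latent = truth$latent, target_latent = truth$target_latent,
         network_labels = truth$network_labels,
         network_centers = as.list(truth$network_centers),
         seeds = as.list(truth$seeds),
         tracking_genes = if (!is.null(panel)) panel$tracking_genes,
         term_peaks = if (!is.null(terms)) as.list(terms$peaks)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  yaml::write_yaml(cfg, file.path(dir, "run.yaml"))
  read_run_config(file.path(dir, "run.yaml"))
}

#' One-command demonstration on synthetic data
#'
#' Simulates the default synthetic world (plus expression panel, term maps
#' and annotation sets derived from the master seed), writes it under
#' `dir/world`, runs the full pipeline into `dir/run`, and returns the
#' stage results.  The demo uses 500 permutations per permutation test to
#' stay quick; all other parameters are the analysis defaults.
#'
#' @param dir output directory.
#' @param seed master seed (default 42).
#' @param n_perm demo-scale permutation count (default 500).
#' @return The [run_all()] result list, invisibly.
#' @export
run_demo <- function(dir, seed = 42L, n_perm = 500L) {
  world <- make_connectivity_world(seed = seed)
  panel <- make_expression_panel(world, seed = seed + 1L)
  terms <- make_term_maps(world, seed = seed + 2L)
  sets <- make_annotation_sets(
    panel$panel$gene_symbols,
    panel$tracking_genes$gene[panel$tracking_genes$beta > 0],
    seed = seed + 3L)
  cfg <- write_world(world, file.path(dir, "world"), panel = panel,
                     terms = terms, sets = sets)
  cfg$out_dir <- file.path(dir, "run")
  cfg$n_perm_geometry <- n_perm
  cfg$n_perm_pls <- n_perm
  cfg$master_seed <- as.integer(seed)
  run_all(cfg)
}
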