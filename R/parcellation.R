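# Winner-take-all assignment of seed voxels to canonical functional
# networks, and per-subdivision summaries of the dominant gradient.

#' Mean BOLD time course of each labeled network
#'
#' @param targets a `group_timeseries` of target (non-seed) voxels, so that
#'   a seed voxel is never correlated with a mean containing itself.
#' @param labels per-target-voxel network label (factor or character); every
#'   level must label at least one voxel.
#' @return network x time matrix of unweighted voxel means, rownames the
#'   network names in level order.
#' @export
network_mean_timecourses <- function(targets, labels) {
  stopifnot(inherits(targets, "group_timeseries"))
  labels <- as.factor(labels)
  if (length(labels) != nrow(targets$values))
    stop("one label per target voxel required")
  empty <- levels(labels)[tabulate(labels, nbins = nlevels(labels)) == 0L]
  if (length(empty))
    stop(sprintf("network(s) with no labeled voxels: %s",
                 paste(empty, collapse = ", ")))
  means <- t(vapply(levels(labels), function(l) {
    colMeans(targets$values[labels == l, , drop = FALSE])
  }, numeric(ncol(targets$values))))
  rownames(means) <- levels(labels)
  means
}

#' Winner-take-all network parcellation of the seed
#'
#' Each seed voxel is assigned to the network whose mean time course it
#' correlates with most strongly (Pearson); ties go to the lowest network
#' index with a warning; zero-variance voxels are labeled `"unassigned"`
#' and excluded from summaries.  Per network the dominant-gradient values of
#' its voxels are summarised (n, mean, sd) and subdivisions are ranked by
#' mean gradient; networks winning no voxel are reported with n = 0 rather
#' than dropped.
#'
#' @param seed a `group_timeseries` of seed voxels.
#' @param network_means network x time matrix (see
#'   [network_mean_timecourses()]).
#' @param gradient per-voxel dominant-gradient values for the seed.
#' @return An object of class `wta_parcellation`: `assignment` (per-voxel
#'   label), `correlations` (voxel x network r), `network_names`, and
#'   `subdivision_summary` (data.frame: network, n_voxels, mean_gradient,
#'   sd_gradient, rank), sorted by mean gradient.
#' @export
winner_take_all <- function(seed, network_means, gradient) {
  stopifnot(inherits(seed, "group_timeseries"))
  if (ncol(seed$values) != ncol(network_means))
    stop("seed series and network means must share the time axis")
  nets <- rownames(network_means)
  r <- row_correlation(seed$values, network_means)
  colnames(r) <- nets
  zero_var <- rowSums(zscore_rows(seed$values)^2) == 0
  best <- apply(r, 1L, function(v) which(v == max(v))[1L])
  n_tied <- sum(apply(r, 1L, function(v) sum(v == max(v)) > 1L) & !zero_var)
  if (n_tied > 0L)
    warning(sprintf(
      "%d voxel(s) tied at the maximum correlation; lowest network index used",
      n_tied))
  assignment <- nets[best]
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance voxel(s) left unassigned",
                    sum(zero_var)))
    assignment[zero_var] <- "unassigned"
  }
  summ <- do.call(rbind, lapply(nets, function(l) {
    g <- gradient[assignment == l]
    data.frame(network = l, n_voxels = length(g),
               mean_gradient = if (length(g)) mean(g) else NA_real_,
               sd_gradient = if (length(g) > 1L) stats::sd(g) else NA_real_)
  }))
  summ$rank <- rank(summ$mean_gradient, na.last = "keep")
  summ <- summ[order(summ$mean_gradient), ]
  rownames(summ) <- NULL
  structure(
    list(assignment = assignment, correlations = r, network_names = nets,
         subdivision_summary = summ),
    class = "wta_parcellation")
}

#' @export
print.wta_parcellation <- function(x, ...) {
  cat(sprintf("<wta_parcellation> %d voxels over %d networks\n",
              length(x$assignment), length(x$network_names)))
  print(x$subdivision_summary, digits = 4)
  invisible(x)
}
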