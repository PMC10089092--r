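# Transcriptome-gradient association: sample-to-gradient sphere mapping,
# first-component PLS regression, permutation testing, gene loadings and
# top-quartile gene selection.
#
# Only the first PLS component is used, computed by the exact closed form
# for a univariate response: the component-1 weight vector is proportional
# to X_centred' y_centred (equivalent to the NIPALS/SIMPLS first component;
# no deflation is needed).

#' Expression panel constructor
#'
#' @param expression sample x gene matrix of normalized expression.
#' @param sample_coords_mm sample x 3 matrix of MNI coordinates.
#' @param sample_ids optional sample identifiers.
#' @param gene_symbols optional gene symbols (default the matrix colnames);
#'   must be unique.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(expression, sample_coords_mm,
                             sample_ids = NULL, gene_symbols = NULL) {
  expression <- as.matrix(expression)
  sample_coords_mm <- as.matrix(sample_coords_mm)
  if (is.null(gene_symbols)) gene_symbols <- colnames(expression)
  if (is.null(gene_symbols))
    gene_symbols <- paste0("G", seq_len(ncol(expression)))
  if (anyDuplicated(gene_symbols)) stop("gene symbols must be unique")
  if (!all(is.finite(expression))) stop("expression must be finite")
  if (nrow(sample_coords_mm) != nrow(expression) ||
      ncol(sample_coords_mm) != 3L)
    stop("one x/y/z coordinate row per sample required")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(expression)))
  colnames(expression) <- gene_symbols
  structure(list(sample_ids = as.character(sample_ids),
                 sample_coords_mm = unname(sample_coords_mm),
                 expression = expression, gene_symbols = gene_symbols),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("<expression_panel> %d samples x %d genes\n",
              nrow(x$expression), ncol(x$expression)))
  invisible(x)
}

#' Map expression samples onto the gradient via spheres
#'
#' For each tissue sample, the mean gradient value over the seed voxels
#' whose centre lies within `radius_mm` (inclusive) of the sample's MNI
#' coordinate.  Samples with no voxel in radius are dropped with a warning.
#'
#' @param panel an [expression_panel()].
#' @param gradient per-voxel gradient values.
#' @param grid the [voxel_grid()] of the gradient.
#' @param radius_mm sphere radius in millimetres (default 3).
#' @return A list with `sample_gradient` (per kept sample), `kept` (logical
#'   per input sample).
#' @export
map_samples_to_gradient <- function(panel, gradient, grid, radius_mm = 3) {
  stopifnot(inherits(panel, "expression_panel"), radius_mm > 0,
            length(gradient) == n_voxels(grid))
  ns <- nrow(panel$expression)
  vals <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    d2 <- rowSums(sweep(grid$coords_mm, 2L, panel$sample_coords_mm[i, ])^2)
    inside <- d2 <= radius_mm^2 + 1e-9
    if (any(inside)) vals[i] <- mean(gradient[inside])
  }
  kept <- !is.na(vals)
  if (!any(kept))
    stop("no sample has a seed voxel within the sphere radius")
  if (any(!kept))
    warning(sprintf("%d sample(s) with no voxel within %g mm dropped",
                    sum(!kept), radius_mm))
  list(sample_gradient = vals[kept], kept = kept)
}

#' First-component PLS fit of expression against the gradient
#'
#' Expression columns and the response are mean-centred (optionally
#' unit-variance scaled); the component-1 weight vector is
#' `w = X_c' y_c / ||X_c' y_c||`, gene scores are `X_c w`, and the sign is
#' flipped so that the score-gradient correlation is non-negative.
#'
#' @param expression sample x gene matrix (or an [expression_panel()]).
#' @param y per-sample gradient values.
#' @param scale unit-variance scale the gene columns first (default `FALSE`:
#'   panels are assumed already normalized).
#' @return An object of class `pls_association` (fit part): `weights`,
#'   `scores`, `loadings`, `r_scores_gradient`, `y`, plus the centred
#'   matrices for reuse.
#' @export
pls1_fit <- function(expression, y, scale = FALSE) {
  if (inherits(expression, "expression_panel"))
    expression <- expression$expression
  X <- as.matrix(expression)
  if (nrow(X) < 3L) stop("need at least 3 samples")
  if (stats::sd(y) == 0) stop("response is constant")
  if (length(y) != nrow(X))
    stop("y must have one value per sample")
  cs <- apply(X, 2L, stats::sd)
  const <- cs == 0
  if (any(const))
    warning(sprintf("%d constant gene column(s) get zero weight",
                    sum(const)))
  Xc <- sweep(X, 2L, colMeans(X))
  if (scale) {
    s <- cs; s[const] <- 1
    Xc <- sweep(Xc, 2L, s, `/`)
  }
  yc <- y - mean(y)
  w <- as.vector(crossprod(Xc, yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("all gene columns are constant")
  w <- w / nw
  scores <- as.vector(Xc %*% w)
  if (stats::cor(scores, y) < 0) {
    w <- -w
    scores <- -scores
  }
  loadings <- gene_loadings(X, scores)
  names(w) <- colnames(X)
  structure(
    list(weights = w, scores = scores, loadings = loadings,
         r_scores_gradient = stats::cor(scores, y),
         y = y, n_samples = nrow(X), scaled = scale),
    class = "pls_association")
}

#' Per-gene loadings: correlation of each gene with the PLS scores
#'
#' @param expression sample x gene matrix.
#' @param scores per-sample component-1 gene scores.
#' @return Named numeric vector of Pearson correlations in [-1, 1];
#'   constant genes get loading 0 and are flagged in the `"constant"`
#'   attribute.
#' @export
gene_loadings <- function(expression, scores) {
  if (inherits(expression, "expression_panel"))
    expression <- expression$expression
  X <- as.matrix(expression)
  const <- apply(X, 2L, stats::sd) == 0
  l <- rep(0, ncol(X))
  if (any(!const))
    l[!const] <- as.vector(stats::cor(X[, !const, drop = FALSE], scores))
  names(l) <- colnames(X)
  attr(l, "constant") <- which(const)
  l
}

#' Permutation test of the PLS score-gradient correlation
#'
#' The response is shuffled across samples, the component-1 fit repeated,
#' and the (sign-aligned, hence non-negative) score-gradient correlation
#' recorded; `p = #(r_null >= r_observed) / n_perm`, one-sided, reported as
#' `< 1/n_perm` when the count is zero.
#'
#' @param expression sample x gene matrix (or [expression_panel()]).
#' @param y per-sample gradient values.
#' @param n_perm permutations (default 5000).
#' @param seed RNG seed.
#' @param exhaustive enumerate all `n!` permutations (n <= 8).
#' @param scale passed to the fit.
#' @return A list `p_perm`, `p_label`, `r_observed`, `r_null`, `n_perm`.
#' @export
pls_permutation_test <- function(expression, y, n_perm = 5000L, seed = NULL,
                                 exhaustive = FALSE, scale = FALSE) {
  if (inherits(expression, "expression_panel"))
    expression <- expression$expression
  X <- as.matrix(expression)
  fit <- pls1_fit(X, y, scale = scale)
  r_obs <- fit$r_scores_gradient
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  if (scale) {
    s <- apply(X, 2L, stats::sd); s[s == 0] <- 1
    Xc <- sweep(Xc, 2L, s, `/`)
  }
  M <- tcrossprod(Xc)                      # scores_perm = M y_perm,c
  if (exhaustive) {
    perms <- t(all_permutations(n))
    n_perm <- ncol(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perms <- replicate(n_perm, sample.int(n))
  }
  Y <- matrix(y[perms], nrow = n)
  Yc <- sweep(Y, 2L, colMeans(Y))
  S <- M %*% Yc
  num <- colSums(S * Yc)
  den <- sqrt(colSums(S^2) * colSums(Yc^2))
  r_null <- abs(num) / den                 # sign-aligned null correlations
  hits <- sum(r_null >= r_obs - 1e-15)
  p <- hits / n_perm
  list(p_perm = p,
       p_label = if (hits == 0) sprintf("<%g", 1 / n_perm) else
         sprintf("%g", p),
       r_observed = r_obs, r_null = r_null, n_perm = n_perm)
}

#' Select strongly contributing genes from loadings
#'
#' Genes are split by loading sign; the top `floor(top_fraction * n)` of the
#' positive loadings (descending) form the PLS+ set and the top
#' `floor(top_fraction * n)` of the negative loadings (most negative first)
#' the PLS- set.  Zero-loading genes belong to neither pool.
#'
#' @param loadings named per-gene loadings.
#' @param top_fraction fraction of each sign pool to keep, in (0, 1);
#'   default 0.25.
#' @return List with `pls_plus` and `pls_minus` gene-name vectors.
#' @export
select_contributing_genes <- function(loadings, top_fraction = 0.25) {
  if (!(top_fraction > 0 && top_fraction < 1))
    stop("top_fraction must be in (0, 1)")
  if (is.null(names(loadings)))
    names(loadings) <- paste0("G", seq_along(loadings))
  pos <- loadings[loadings > 0]
  neg <- loadings[loadings < 0]
  if (length(pos) == 0L) warning("no positive-loading genes: PLS+ empty")
  if (length(neg) == 0L) warning("no negative-loading genes: PLS- empty")
  take <- function(v, decreasing) {
    k <- floor(top_fraction * length(v))
    names(v)[order(v * if (decreasing) -1 else 1,
                   seq_along(v))][seq_len(k)]
  }
  list(pls_plus = if (length(pos)) take(pos, TRUE) else character(0),
       pls_minus = if (length(neg)) take(neg, FALSE) else character(0))
}

#' Full transcriptome-gradient association
#'
#' Maps samples onto the gradient ([map_samples_to_gradient()]), fits the
#' first PLS component ([pls1_fit()]), assesses it by sample-shuffle
#' permutation ([pls_permutation_test()]) and selects the strongly
#' contributing PLS+/PLS- genes ([select_contributing_genes()]).
#'
#' @param panel an [expression_panel()].
#' @param gradient per-voxel gradient values (or a `gradient_set`).
#' @param grid the seed [voxel_grid()] (ignored for a `gradient_set`).
#' @param radius_mm sample sphere radius (default 3).
#' @param n_perm permutations (default 5000).
#' @param seed RNG seed.
#' @param top_fraction gene-selection fraction (default 0.25).
#' @param scale unit-variance scale gene columns (default `FALSE`).
#' @return A `pls_association` with, additionally, `sample_gradient`,
#'   `kept`, `p_perm`, `p_label`, `n_perm`, `pls_plus`, `pls_minus`.
#' @export
pls_gradient_association <- function(panel, gradient, grid = NULL,
                                     radius_mm = 3, n_perm = 5000L,
                                     seed = NULL, top_fraction = 0.25,
                                     scale = FALSE) {
  if (inherits(gradient, "gradient_set")) {
    grid <- gradient$grid
    gradient <- dominant_gradient(gradient)
  }
  mapped <- map_samples_to_gradient(panel, gradient, grid, radius_mm)
  X <- panel$expression[mapped$kept, , drop = FALSE]
  y <- mapped$sample_gradient
  fit <- pls1_fit(X, y, scale = scale)
  perm <- pls_permutation_test(X, y, n_perm = n_perm, seed = seed,
                               scale = scale)
  sel <- select_contributing_genes(fit$loadings, top_fraction)
  fit$sample_gradient <- y
  fit$kept <- mapped$kept
  fit$p_perm <- perm$p_perm
  fit$p_label <- perm$p_label
  fit$n_perm <- perm$n_perm
  fit$pls_plus <- sel$pls_plus
  fit$pls_minus <- sel$pls_minus
  fit
}

#' @export
print.pls_association <- function(x, ...) {
  cat(sprintf("<pls_association> %d samples x %d genes\n",
              x$n_samples, length(x$weights)))
  cat(sprintf("  component-1 score-gradient r = %.4f", x$r_scores_gradient))
  if (!is.null(x$p_perm))
    cat(sprintf(", p_perm %s (%d permutations)",
                if (x$p_perm == 0) x$p_label else sprintf("= %s", x$p_label),
                x$n_perm))
  cat("\n")
  if (!is.null(x$pls_plus))
    cat(sprintf("  PLS+: %d genes, PLS-: %d genes\n",
                length(x$pls_plus), length(x$pls_minus)))
  invisible(x)
}

#' @export
summary.pls_association <- function(object, ...) {
  set <- rep("none", length(object$loadings))
  names(set) <- names(object$loadings)
  if (!is.null(object$pls_plus)) set[object$pls_plus] <- "PLS+"
  if (!is.null(object$pls_minus)) set[object$pls_minus] <- "PLS-"
  out <- data.frame(gene = names(object$loadings),
                    weight = unname(object$weights),
                    loading = unname(object$loadings),
                    set = unname(set))
  out[order(-out$loading), ]
}

#' Scatterplot of gene scores against the gradient
#' @param x a `pls_association`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pls_association <- function(x, ...) {
  graphics::plot(x$y, x$scores, xlab = "sample gradient value",
                 ylab = "component-1 gene score", ...)
  graphics::abline(stats::lm(x$scores ~ x$y), lty = 2)
  invisible(x)
}
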