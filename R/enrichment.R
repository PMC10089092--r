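# Over-representation analysis of gene lists against annotation sets:
# Fisher's exact test with Benjamini-Hochberg correction.  The background
# universe is the analyzed gene panel, so enrichment is conditional on what
# could have been selected.

#' Fisher's exact over-representation of a gene list in annotation sets
#'
#' For each annotation set (intersected with the background first), the
#' 2x2 table (in-query & in-set, in-query & not, not-query & in-set,
#' not-query & not) is tested with a two-sided Fisher's exact test
#' (minimum-likelihood convention).  The odds ratio is the sample odds ratio
#' with a Haldane 0.5 correction applied when any cell is zero.  q-values
#' are Benjamini-Hochberg adjusted across the sets of this call (one FDR
#' family per query and database).
#'
#' @param query character vector of query genes (must be a subset of
#'   `background`).
#' @param sets named list of gene-symbol vectors (see
#'   [read_annotation_sets()]).
#' @param background character vector: the gene universe (e.g. the analyzed
#'   panel).
#' @param q_threshold significance threshold on q (default 0.05).
#' @return A data.frame of class `enrichment_result`, one row per tested
#'   set, sorted by p: set_name, n_overlap, n_query, n_set_in_background,
#'   n_background, rich_factor (n_overlap / n_set_in_background),
#'   odds_ratio, p_value, q_value, significant.
#' @export
fisher_enrichment <- function(query, sets, background, q_threshold = 0.05) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (length(query) == 0L || length(background) == 0L)
    stop("query and background must be non-empty")
  if (!all(query %in% background))
    stop("query genes must all belong to the background universe")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  sets_bg <- lapply(sets, intersect, background)
  empty <- vapply(sets_bg, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sprintf("skipping %d set(s) with no background overlap: %s",
                    sum(empty),
                    paste(names(sets)[empty], collapse = ", ")))
    sets_bg <- sets_bg[!empty]
  }
  if (length(sets_bg) == 0L)
    stop("no annotation set overlaps the background")
  N <- length(background)
  nq <- length(query)
  rows <- lapply(names(sets_bg), function(nm) {
    g <- sets_bg[[nm]]
    a <- length(intersect(query, g))
    b <- nq - a
    cc <- length(g) - a
    d <- N - nq - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE),
                            alternative = "two.sided")$p.value
    cells <- c(a, b, cc, d)
    if (any(cells == 0)) cells <- cells + 0.5
    data.frame(set_name = nm, n_overlap = a, n_query = nq,
               n_set_in_background = length(g), n_background = N,
               rich_factor = a / length(g),
               odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- fdr_bh(out$p_value)
  out$significant <- out$q_value <= q_threshold
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values numeric p-values in [0, 1].
#' @return Monotone step-up adjusted q-values, capped at 1.
#' @export
fdr_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d sets tested, %d significant\n",
              nrow(x), sum(x$significant)))
  print.data.frame(utils::head(x, 10L), digits = 4)
  invisible(x)
}
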