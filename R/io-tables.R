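# Plain-text table formats: tab-delimited expression panels (sample_id, x,
# y, z, then one column per gene, header required) and GMT-style annotation
# sets.

#' Read an expression panel from a tab-delimited table
#'
#' Expected dialect: header row; first column `sample_id`, then `x`, `y`,
#' `z` MNI coordinates in mm, then one column per gene.
#'
#' @param path file path.
#' @return An [expression_panel()].
#' @export
read_expression_panel <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 5L || !all(c("x", "y", "z") == names(tab)[2:4]))
    stop(sprintf(
      "'%s': expected columns sample_id, x, y, z, then genes", path))
  expression_panel(as.matrix(tab[, -(1:4), drop = FALSE]),
                   as.matrix(tab[, 2:4]),
                   sample_ids = tab[[1L]],
                   gene_symbols = names(tab)[-(1:4)])
}

#' Write an expression panel to a tab-delimited table
#' @param panel an [expression_panel()].
#' @param path output path.
#' @export
write_expression_panel <- function(panel, path) {
  tab <- data.frame(sample_id = panel$sample_ids,
                    x = panel$sample_coords_mm[, 1L],
                    y = panel$sample_coords_mm[, 2L],
                    z = panel$sample_coords_mm[, 3L],
                    panel$expression, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read annotation gene sets (GMT-like)
#'
#' Accepts both the GMT dialect
#' `set_name<TAB>description<TAB>gene1<TAB>gene2...` and the comma-list form
#' `set_name<TAB>gene1,gene2,...` (a comma-separated member field, with or
#' without a description column).
#'
#' @param path file path.
#' @return Named list of gene-symbol character vectors; set names unique,
#'   sets non-empty.
#' @export
read_annotation_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop(sprintf("'%s': malformed annotation line: %s", path, ln))
    nm <- f[1L]
    rest <- f[-1L]
    if (length(rest) >= 2L && !grepl(",", rest[1L], fixed = TRUE))
      rest <- rest[-1L]                     # drop description column
    genes <- unlist(strsplit(rest, ",", fixed = TRUE))
    genes <- unique(trimws(genes))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop(sprintf("'%s': empty gene set '%s'", path, nm))
    sets[[nm]] <- genes
  }
  if (anyDuplicated(names(sets)))
    stop(sprintf("'%s': duplicated set names", path))
  sets
}

#' Write annotation gene sets in GMT format
#' @param sets named list of gene-symbol vectors.
#' @param path output path.
#' @param descriptions optional per-set description column (default `"na"`).
#' @export
write_annotation_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
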