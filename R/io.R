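#' Read and write the plain-text interchange formats
#'
#' All pipeline stages exchange data as tab-separated text so that any run
#' can be inspected and re-fed from disk: expression matrices (first column
#' the gene id, remaining columns samples), two-column sample-to-group
#' tables, GMT pathway files and generic headered TSV tables.
#'
#' @param x object to serialize (matrix or data.frame as appropriate).
#' @param path file path.
#' @name fibropath-io
NULL

#' @rdname fibropath-io
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname fibropath-io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname fibropath-io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname fibropath-io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a pathway set as a GMT file
#'
#' GMT is the tab-separated gene-set format: one set per line with the set
#' id, a free-text description and then the member genes.
#'
#' @param pathways named list of character vectors of member genes.
#' @param path file path.
#' @param descriptions optional character vector of descriptions (recycled
#'   from the set ids when missing).
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  descriptions <- descriptions %||% names(pathways)
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT pathway file
#'
#' @param path file path.
#' @return Named list of character vectors (member genes); the description
#'   column is kept in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  assert_that(!anyDuplicated(ids), "duplicate pathway ids in GMT file")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}
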