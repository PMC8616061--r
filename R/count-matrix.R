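#' Construct a validated gene x cell count matrix
#'
#' The basic container for raw single-cell counts: a nonnegative integer
#' matrix with unique gene (row) and cell (column) names, plus optional
#' per-cell metadata (e.g. time point, condition, anatomical site).
#'
#' @param values Nonnegative integer matrix, genes in rows, cells in columns,
#'   with unique `rownames` and `colnames`.
#' @param cell_meta Optional `data.frame` with one row per cell, aligned to
#'   the columns of `values` (row names matching cell names, or same order).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (the integer matrix) and `cell_meta` (a data.frame or `NULL`).
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' cm <- count_matrix(m)
#' dim(cm)
#' @export
count_matrix <- function(values, cell_meta = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (any(is.na(values))) stop("count matrix contains NA entries")
  if (any(values < 0)) stop("count matrix contains negative entries")
  if (any(values != round(values))) stop("count matrix contains non-integer entries")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count matrix requires gene (row) and cell (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene names in count matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicated cell names in count matrix")
  storage.mode(values) <- "double"  # keeps large counts exact, avoids int overflow in sums
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != ncol(values))
      stop("cell_meta rows must match number of cells")
    rownames(cell_meta) <- colnames(values)
  }
  structure(list(counts = values, cell_meta = cell_meta), class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$cell_meta))
    cat("  cell_meta:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Gene names of a count matrix
#' @param x A `count_matrix`.
#' @return Character vector of gene names.
#' @export
gene_names <- function(x) rownames(x$counts)

#' Cell names of a count matrix
#' @param x A `count_matrix`.
#' @return Character vector of cell names.
#' @export
cell_names <- function(x) colnames(x$counts)

# Accepts a count_matrix or a plain named matrix; returns the raw matrix.
as_count_values <- function(x) {
  if (inherits(x, "count_matrix")) return(x$counts)
  if (is.matrix(x)) return(count_matrix(x)$counts)
  stop("expected a count_matrix or a named matrix")
}
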