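#' Read a gene x cell count matrix
#'
#' Supports the sparse MatrixMarket triplet format (with `genes.tsv` and
#' `barcodes.tsv` name sidecars next to the `.mtx` file) and dense CSV/TSV
#' with genes in rows, a header row of cell names and gene names in the
#' first column.
#'
#' @param path Path to the `.mtx`, `.csv` or `.tsv` file.
#' @param format One of `"mtx"`, `"csv"`, `"tsv"`; guessed from the file
#'   extension by default.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension: ", ext))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    gf <- file.path(dir, "genes.tsv")
    bf <- file.path(dir, "barcodes.tsv")
    if (!file.exists(gf) || !file.exists(bf))
      stop("MTX sidecar files genes.tsv / barcodes.tsv not found in ", dir)
    genes <- readLines(gf)
    cells <- readLines(bf)
    if (length(genes) != nrow(m))
      stop("genes.tsv has ", length(genes), " entries but matrix has ",
           nrow(m), " rows")
    if (length(cells) != ncol(m))
      stop("barcodes.tsv has ", length(cells), " entries but matrix has ",
           ncol(m), " columns")
    dimnames(m) <- list(genes, cells)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, row.names = NULL)
    m <- as.matrix(df[, -1, drop = FALSE])
    rn <- as.character(df[[1]])
    if (anyDuplicated(rn)) stop("duplicated gene names in ", path)
    rownames(m) <- rn
  }
  count_matrix(m)
}

#' Write a count matrix as MatrixMarket MTX plus name sidecars
#'
#' @param x A [count_matrix()] or named matrix.
#' @param path Output `.mtx` path; `genes.tsv` and `barcodes.tsv` are written
#'   alongside it.
#' @return `path`, invisibly.
#' @export
write_counts_mtx <- function(x, path) {
  m <- as_count_values(x)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  writeLines(rownames(m), file.path(dirname(path), "genes.tsv"))
  writeLines(colnames(m), file.path(dirname(path), "barcodes.tsv"))
  invisible(path)
}

#' Write a count matrix as dense CSV/TSV with gene rows
#'
#' @param x A [count_matrix()] or named matrix.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts_dense <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  m <- as_count_values(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene signature (one gene identifier per line)
#'
#' @param path Text file path.
#' @return `read_signature`: character vector of unique gene names.
#' @export
read_signature <- function(path) {
  g <- trimws(readLines(path))
  g <- g[nzchar(g)]
  if (length(g) == 0) stop("empty signature file: ", path)
  if (anyDuplicated(g)) stop("duplicated genes in signature file: ", path)
  g
}

#' @rdname read_signature
#' @param genes Character vector of gene names.
#' @export
write_signature <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Construct a ligand-receptor database
#'
#' @param df `data.frame` with character columns `pathway`, `ligand`,
#'   `receptor`; multi-subunit ligands/receptors are comma-joined gene names.
#' @return The validated `data.frame` with class `lr_database`.
#' @export
lr_database <- function(df) {
  req <- c("pathway", "ligand", "receptor")
  if (!all(req %in% names(df)))
    stop("lr_database needs columns ", paste(req, collapse = ", "))
  if (nrow(df) == 0) stop("lr_database is empty")
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor)))
    stop("empty ligand or receptor subunit list")
  key <- paste(df$pathway, df$ligand, df$receptor)
  if (anyDuplicated(key)) stop("duplicated (pathway, ligand, receptor) entries")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("lr_database", "data.frame")
  df
}

#' @rdname lr_database
#' @param path TSV path with columns pathway, ligand, receptor.
#' @export
read_lr_database <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lr_database(df)
}

#' @rdname lr_database
#' @param db An `lr_database`.
#' @export
write_lr_database <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Split comma-joined subunits into a character vector.
split_subunits <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1]])
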