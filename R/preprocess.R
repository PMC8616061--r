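#' Preprocess raw counts: top-gene selection, cell filter, log transform
#'
#' The standard pre-clustering recipe: (1) keep the `top_n_genes` genes with
#' the largest total count over all cells (ties at the boundary broken by
#' gene name, ascending, for platform-independent determinism); (2) among
#' the kept genes, drop cells that express (count > 0) fewer than
#' `ceiling(min_gene_fraction * kept_gene_count)` genes; (3) transform the
#' surviving counts as `log(pseudocount + count)` (natural log).
#'
#' The cell filter is evaluated against the kept gene panel by default;
#' `filter_on = "all"` instead counts expressed genes over the full
#' pre-selection panel (both conventions are found in the wild).
#'
#' @param raw A [count_matrix()] or named matrix of raw counts.
#' @param top_n_genes Number of top-expressed genes to keep (default 3000;
#'   all genes if the matrix has fewer).
#' @param min_gene_fraction Minimum fraction of panel genes a cell must
#'   express to be kept (default 0.05).
#' @param pseudocount Added before the log transform (default 1, so zero
#'   counts map to exactly 0).
#' @param filter_on `"kept"` (default) or `"all"`: the gene panel against
#'   which the cell filter fraction is evaluated.
#' @return A list with `counts` (the filtered [count_matrix()]) and `expr`
#'   (the log-transformed numeric matrix, genes x cells, with the applied
#'   configuration in `attr(, "preprocess")`).
#' @examples
#' cfg <- sim_config(cells_per_state = rep(20L, 4), seed = 1)
#' ds <- generate_emt_dataset(cfg)
#' pp <- preprocess(ds$counts, top_n_genes = 200)
#' dim(pp$expr)
#' @export
preprocess <- function(raw, top_n_genes = 3000, min_gene_fraction = 0.05,
                       pseudocount = 1, filter_on = c("kept", "all")) {
  filter_on <- match.arg(filter_on)
  m <- as_count_values(raw)
  meta <- if (inherits(raw, "count_matrix")) raw$cell_meta else NULL
  if (top_n_genes < 2) stop("top_n_genes must be >= 2")
  if (min_gene_fraction < 0 || min_gene_fraction >= 1)
    stop("min_gene_fraction must be in [0, 1)")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty count matrix")

  totals <- rowSums(m)
  ord <- order(-totals, rownames(m))   # ties at boundary -> lexicographic name
  keep_genes <- sort(ord[seq_len(min(top_n_genes, nrow(m)))])
  kept <- m[keep_genes, , drop = FALSE]

  panel <- if (filter_on == "kept") kept else m
  n_expressed <- colSums(panel > 0)
  need <- ceiling(min_gene_fraction * nrow(panel))
  keep_cells <- n_expressed >= need
  if (!any(keep_cells))
    stop("all cells removed by the minimum-expressed-gene filter")
  kept <- kept[, keep_cells, drop = FALSE]
  if (!is.null(meta)) meta <- meta[keep_cells, , drop = FALSE]

  expr <- log(pseudocount + kept)
  attr(expr, "preprocess") <- list(top_n_genes = top_n_genes,
                                   min_gene_fraction = min_gene_fraction,
                                   pseudocount = pseudocount,
                                   filter_on = filter_on)
  list(counts = count_matrix(kept, cell_meta = meta), expr = expr)
}
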