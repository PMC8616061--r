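#' Recovery-curve (AUC) scoring of a gene signature per cell
#'
#' For every cell, all genes are ranked by expression, descending, with ties
#' broken by gene name ascending so the ranking is fully deterministic. The
#' recovery curve R(i) counts how many signature genes appear among the top i
#' ranked genes, for i = 1..`top_k`. The score is the area under this step
#' curve normalized by its maximum possible value,
#' `sum_{i=1..top_k} min(i, |signature|)`, giving a value in [0, 1] that
#' depends only on the within-cell expression ranks.
#'
#' Signature genes absent from the matrix are dropped with a warning and the
#' normalizer uses the retained signature size.
#'
#' @param expr Numeric genes x cells matrix (typically log expression; only
#'   ranks matter).
#' @param signature Character vector of signature gene names (no duplicates).
#' @param top_k Number of top-ranked genes forming the scoring window.
#'   Default: all genes.
#' @return Numeric vector of per-cell scores in [0, 1], named by cell, with
#'   attributes `signature_size` (retained size) and `top_k`.
#' @examples
#' expr <- matrix(c(5, 4, 3, 2, 1), 5, 1,
#'                dimnames = list(c("A", "B", "C", "D", "E"), "cell1"))
#' score_signature(expr, c("A", "C"), top_k = 3)  # 0.8
#' @export
score_signature <- function(expr, signature, top_k = nrow(expr)) {
  if (anyDuplicated(signature)) stop("signature contains duplicated genes")
  if (length(signature) == 0) stop("empty signature")
  present <- signature %in% rownames(expr)
  if (!any(present))
    stop("no signature gene present in the expression matrix")
  if (any(!present))
    warning(sum(!present), " signature gene(s) absent from matrix, dropped")
  sig <- signature[present]
  if (top_k < 1 || top_k > nrow(expr))
    stop("top_k must be between 1 and the number of genes")
  genes <- rownames(expr)
  s <- length(sig)
  denom <- sum(pmin(seq_len(top_k), s))
  sig_idx <- genes %in% sig
  scores <- vapply(seq_len(ncol(expr)), function(c) {
    ord <- order(-expr[, c], genes)       # descending expr, name-ascending ties
    pos <- which(sig_idx[ord])            # ranks of signature genes
    pos <- pos[pos <= top_k]
    # gene at rank p contributes to R(i) for i = p..top_k
    sum(top_k - pos + 1) / denom
  }, numeric(1))
  names(scores) <- colnames(expr)
  attr(scores, "signature_size") <- s
  attr(scores, "top_k") <- top_k
  scores
}

#' Epithelial and mesenchymal scores for every cell
#'
#' Convenience wrapper running [score_signature()] for the epithelial
#' (downregulated) and mesenchymal (upregulated) EMT signatures.
#'
#' @param expr Numeric genes x cells matrix.
#' @param sig_e,sig_m Epithelial and mesenchymal gene vectors.
#' @param top_k Scoring window; default all genes.
#' @return `data.frame` with columns `cell`, `E`, `M`.
#' @export
score_emt <- function(expr, sig_e, sig_m, top_k = nrow(expr)) {
  data.frame(cell = colnames(expr),
             E = as.numeric(score_signature(expr, sig_e, top_k)),
             M = as.numeric(score_signature(expr, sig_m, top_k)),
             stringsAsFactors = FALSE)
}

#' Per-cluster mean and standard deviation of signature scores
#'
#' Summaries used for projecting clusters into the E-M score plane (circle
#' centers = means, radii = standard deviations). The sd is the population
#' (n-denominator) standard deviation; clusters with fewer than two cells get
#' sd 0 with a warning.
#'
#' @param scores `data.frame` of per-cell scores (e.g. from [score_emt()]);
#'   all numeric columns are summarized.
#' @param labels Per-cell cluster labels aligned with the rows of `scores`.
#' @return `data.frame` with one row per cluster: `cluster`, `n`, then
#'   `<score>_mean` and `<score>_sd` per score column.
#' @export
summarize_by_cluster <- function(scores, labels) {
  if (nrow(scores) != length(labels))
    stop("labels must cover all scored cells")
  num_cols <- names(scores)[vapply(scores, is.numeric, logical(1))]
  cl <- sort(unique(labels))
  out <- data.frame(cluster = cl,
                    n = as.integer(table(factor(labels, levels = cl))))
  if (any(out$n < 2))
    warning("cluster(s) with < 2 cells: sd reported as 0")
  for (col in num_cols) {
    out[[paste0(col, "_mean")]] <-
      vapply(cl, function(k) mean(scores[[col]][labels == k]), numeric(1))
    out[[paste0(col, "_sd")]] <-
      vapply(cl, function(k) pop_sd(scores[[col]][labels == k]), numeric(1))
  }
  out
}
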