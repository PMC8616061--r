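#' Transcriptional diversity: number of expressed genes per cell
#'
#' Counts, for each cell, the genes with at least one raw mRNA count. This
#' quantity is defined on raw counts and is independent of any
#' normalization.
#'
#' @param raw A [count_matrix()] or named matrix of raw counts.
#' @return Named integer vector, one entry per cell.
#' @export
transcriptional_diversity <- function(raw) {
  m <- as_count_values(raw)
  colSums(m >= 1)
}

#' Correlation-thresholded gene-gene network
#'
#' Connects two genes when the absolute correlation of their expression
#' across all cells is at least `tau` (default 0.4, a conventional cutoff
#' filtering weakly correlated pairs). Genes with zero variance carry no
#' edges.
#'
#' @param expr Numeric genes x cells matrix (log expression).
#' @param tau Absolute-correlation threshold in (0, 1].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list of class `gene_network`: `genes`, `adjacency` (logical
#'   genes x genes, no self-edges), `tau`, `method`.
#' @export
build_gene_network <- function(expr, tau = 0.4,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  if (ncol(expr) < 3) stop("need at least 3 cells to estimate correlations")
  v <- apply(expr, 1, stats::var)
  ok <- v > 0
  A <- matrix(FALSE, nrow(expr), nrow(expr),
              dimnames = list(rownames(expr), rownames(expr)))
  if (sum(ok) >= 2) {
    cc <- stats::cor(t(expr[ok, , drop = FALSE]), method = method)
    A[ok, ok] <- abs(cc) >= tau
  }
  diag(A) <- FALSE
  structure(list(genes = rownames(expr), adjacency = A, tau = tau,
                 method = method), class = "gene_network")
}

#' Single-cell energy over a gene network
#'
#' Each gene's expression is rescaled per gene to z in [0, 1] by dividing by
#' the gene's maximum over cells (0 if that maximum is 0). The energy of
#' cell c is an entropy-like sum over expressed, networked genes:
#' \deqn{E_c = \sum_{i: z_{ic} > 0,\, N(i) \neq \emptyset}
#'       -z_{ic} \, \ln\!\big( z_{ic} / \textstyle\sum_{j \in N(i)} z_{jc} \big)}
#' with a term set to 0 when its neighbor sum is 0. Isolated genes and
#' silent cells contribute nothing; the energy is maximized when many
#' network-connected genes are simultaneously highly expressed.
#'
#' @param expr Numeric genes x cells matrix; must contain every network
#'   gene.
#' @param net A `gene_network` built on a subset of the matrix genes.
#' @return Named numeric vector of per-cell energies.
#' @export
single_cell_energy <- function(expr, net) {
  if (!all(net$genes %in% rownames(expr)))
    stop("network gene(s) absent from the expression matrix")
  X <- expr[net$genes, , drop = FALSE]
  mx <- apply(X, 1, max)
  Z <- X / ifelse(mx > 0, mx, 1)
  Z[mx == 0, ] <- 0
  A <- net$adjacency * 1          # numeric for matrix product
  deg <- rowSums(A)
  S <- A %*% Z                    # neighbor sums per gene x cell
  term <- matrix(0, nrow(Z), ncol(Z))
  use <- Z > 0 & S > 0 & deg > 0
  term[use] <- -Z[use] * log(Z[use] / S[use])
  en <- colSums(term)
  names(en) <- colnames(expr)
  en
}

#' EMT circuit energy
#'
#' The single-cell energy computed on the expression matrix restricted to
#' the union of the epithelial and mesenchymal signature genes: the
#' correlation network is rebuilt on that restricted panel and the energy
#' evaluated there. Because the energy grows with broad co-expression of
#' networked genes, it is maximized in cells expressing both programs at
#' once, i.e. in states with high E-M plasticity.
#'
#' @param expr Numeric genes x cells matrix (log expression).
#' @param sig_e,sig_m Epithelial and mesenchymal signature gene vectors; at
#'   least two of their union must be present in the matrix.
#' @param tau Correlation threshold for the restricted network (default
#'   0.4).
#' @param method Correlation method, as in [build_gene_network()].
#' @return Named numeric vector of per-cell EMT circuit energies.
#' @export
emt_circuit_energy <- function(expr, sig_e, sig_m, tau = 0.4,
                               method = c("pearson", "spearman")) {
  genes <- intersect(union(sig_e, sig_m), rownames(expr))
  if (length(genes) < 2)
    stop("fewer than 2 signature genes present in the expression matrix")
  sub <- expr[genes, , drop = FALSE]
  net <- build_gene_network(sub, tau = tau, method = method)
  single_cell_energy(sub, net)
}
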