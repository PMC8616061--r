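# Shared fixtures and independent oracles for the test suite.

# Small simulation config for fast tests.
small_config <- function(seed = 1, cells = 30L, ...) {
  sim_config(cells_per_state = rep(cells, 4),
             n_epithelial_genes = 40, n_mesenchymal_genes = 60,
             n_housekeeping_genes = 50, seed = seed, ...)
}

# Independent brute-force recovery-curve AUC: literal step-curve enumeration.
# For each i in 1..top_k count the signature genes among the top-i ranked
# genes, then sum and normalize by sum(min(i, |signature|)).
brute_force_auc <- function(expr_col, genes, signature, top_k) {
  stopifnot(length(expr_col) == length(genes))
  ranking <- genes[order(-expr_col, genes)]
  sig <- intersect(signature, genes)
  R <- vapply(seq_len(top_k), function(i)
    length(intersect(sig, ranking[seq_len(i)])), numeric(1))
  R_max <- vapply(seq_len(top_k), function(i) min(i, length(sig)), numeric(1))
  sum(R) / sum(R_max)
}

# Adjusted Rand index between two labelings (Hubert & Arabie closed form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Map recovered clusters to true states by majority vote; returns the true
# state assigned to each cluster id.
majority_state <- function(labels, truth) {
  vapply(sort(unique(labels)), function(k) {
    tt <- table(truth[labels == k])
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
}

# Toy count matrix with explicit dimnames.
toy_counts <- function(values, genes = NULL, cells = NULL) {
  genes <- genes %||% paste0("G", seq_len(if (is.matrix(values)) nrow(values)
                                          else length(values)))
  n_cells <- if (is.null(cells)) length(values) %/% length(genes)
             else length(cells)
  cells <- cells %||% paste0("C", seq_len(n_cells))
  matrix(values, nrow = length(genes), ncol = length(cells),
         dimnames = list(genes, cells))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
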