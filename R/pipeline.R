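#' Run the full EMT analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> signature scoring ->
#' consensus clustering + trajectory -> diversity/energy -> ligand-receptor
#' communication -> group statistics, returning one result bundle. All
#' stochastic stages are seeded from `seed`, so reruns with the same
#' configuration reproduce the bundle.
#'
#' @param input Either a [sim_config()] (synthetic run) or a list with
#'   elements `counts` (a [count_matrix()]), `sig_e`, `sig_m` (gene
#'   vectors) and optionally `lr_db` (an [lr_database()]).
#' @param top_n_genes,min_gene_fraction,pseudocount Preprocessing
#'   parameters, see [preprocess()].
#' @param top_k Signature-scoring window; `NULL` (default) uses all kept
#'   genes.
#' @param n_runs,k_min,k_max,delta Clustering/trajectory parameters, see
#'   [build_consensus()], [select_k()], [soft_cluster()].
#' @param tau Correlation threshold for the gene networks.
#' @param Kh,nperm,alpha Communication parameters, see
#'   [communication_probability()], [permutation_significance()],
#'   [interaction_strengths()].
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV/JSON.
#' @return A list of class `emplex_result` with elements `counts`, `expr`,
#'   `scores`, `cluster_summary`, `consensus`, `k`, `membership`,
#'   `trajectory`, `diversity`, `energy`, `emt_energy`, `communication`,
#'   `strengths`, `energy_tests`, `summary` (per-cluster table along the
#'   trajectory order) and `params`.
#' @examples
#' \donttest{
#' res <- run_emt_pipeline(sim_config(cells_per_state = rep(40L, 4), seed = 3),
#'                         n_runs = 24, nperm = 30, seed = 3)
#' res$summary
#' }
#' @export
run_emt_pipeline <- function(input,
                             top_n_genes = 3000, min_gene_fraction = 0.05,
                             pseudocount = 1, top_k = NULL,
                             n_runs = 50, k_min = 3, k_max = 6, delta = 0.1,
                             tau = 0.4, Kh = 0.5, nperm = 100, alpha = 0.05,
                             seed = 1L, out_dir = NULL) {
  if (inherits(input, "sim_config")) {
    dataset <- generate_emt_dataset(input)
    counts <- dataset$counts
    sig_e <- dataset$signatures$epithelial
    sig_m <- dataset$signatures$mesenchymal
    lr_db <- dataset$lr_db
    truth <- dataset$true_state
  } else {
    counts <- input$counts
    sig_e <- input$sig_e
    sig_m <- input$sig_m
    lr_db <- input$lr_db %||% NULL
    truth <- NULL
    dataset <- NULL
  }

  pp <- preprocess(counts, top_n_genes = top_n_genes,
                   min_gene_fraction = min_gene_fraction,
                   pseudocount = pseudocount)
  expr <- pp$expr
  if (is.null(top_k)) top_k <- nrow(expr)

  scores <- suppressWarnings(score_emt(expr, sig_e, sig_m, top_k = top_k))

  cons <- build_consensus(expr, n_runs = n_runs, seed = seed)
  k <- select_k(cons, k_min = k_min, k_max = min(k_max, ncol(expr) - 1))
  memb <- soft_cluster(cons, k, delta = delta, seed = seed + 1L)
  memb <- drop_empty_clusters(memb)   # vacuous factor components, if any
  k <- ncol(memb$H)
  csum <- summarize_by_cluster(scores, memb$hard_label)
  traj <- infer_trajectory(memb, csum)

  diversity <- transcriptional_diversity(pp$counts)
  net <- build_gene_network(expr, tau = tau)
  energy <- single_cell_energy(expr, net)
  emt_energy <- suppressWarnings(
    emt_circuit_energy(expr, sig_e, sig_m, tau = tau))

  comm <- NULL; strengths <- NULL
  if (!is.null(lr_db)) {
    comm <- suppressWarnings(
      permutation_significance(pp$counts, memb$hard_label, lr_db,
                               Kh = Kh, nperm = nperm, seed = seed + 2L))
    strengths <- interaction_strengths(comm, alpha = alpha)
  }

  energy_tests <- compare_along_trajectory(emt_energy, memb$hard_label,
                                           traj$cluster_order)

  ord <- traj$cluster_order
  summary_tab <- data.frame(
    position = seq_along(ord) - 1,
    cluster = ord,
    n_cells = as.integer(table(factor(memb$hard_label, levels = ord))),
    E_mean = csum$E_mean[match(ord, csum$cluster)],
    M_mean = csum$M_mean[match(ord, csum$cluster)],
    diversity_mean = vapply(ord, function(c)
      mean(diversity[memb$hard_label == c]), numeric(1)),
    energy_mean = vapply(ord, function(c)
      mean(energy[memb$hard_label == c]), numeric(1)),
    emt_energy_mean = vapply(ord, function(c)
      mean(emt_energy[memb$hard_label == c]), numeric(1)))
  if (!is.null(strengths)) {
    summary_tab$outgoing <-
      strengths$strengths$outgoing[match(ord, strengths$strengths$cluster)]
    summary_tab$incoming <-
      strengths$strengths$incoming[match(ord, strengths$strengths$cluster)]
  }

  res <- structure(list(
    counts = pp$counts, expr = expr, scores = scores,
    cluster_summary = csum, consensus = cons, k = k, membership = memb,
    trajectory = traj, diversity = diversity, energy = energy,
    emt_energy = emt_energy, communication = comm, strengths = strengths,
    energy_tests = energy_tests, summary = summary_tab,
    truth = truth, dataset = dataset,
    params = list(top_n_genes = top_n_genes,
                  min_gene_fraction = min_gene_fraction,
                  pseudocount = pseudocount, top_k = top_k, n_runs = n_runs,
                  k_min = k_min, k_max = k_max, delta = delta, tau = tau,
                  Kh = Kh, nperm = nperm, alpha = alpha, seed = seed)),
    class = "emplex_result")

  if (!is.null(out_dir)) write_result_bundle(res, out_dir)
  res
}

#' @export
print.emplex_result <- function(x, ...) {
  cat(sprintf("<emplex_result> %d genes x %d cells, k = %d clusters\n",
              nrow(x$expr), ncol(x$expr), x$k))
  cat("trajectory:", paste(x$trajectory$cluster_order, collapse = " -> "), "\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' TSV per tabular stage output plus a JSON summary (parameters, selected k,
#' trajectory order, per-cluster summary).
#'
#' @param res An `emplex_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$scores, "scores.tsv")
  wt(res$cluster_summary, "cluster_summary.tsv")
  wt(data.frame(cell = colnames(res$expr),
                cluster = res$membership$hard_label,
                transition = res$membership$transition_flag,
                pseudotime = res$trajectory$pseudotime,
                diversity = res$diversity,
                energy = res$energy,
                emt_energy = res$emt_energy), "cells.tsv")
  wt(as.data.frame(res$membership$H), "membership.tsv")
  wt(res$energy_tests, "energy_tests.tsv")
  wt(res$summary, "summary.tsv")
  if (!is.null(res$strengths)) {
    wt(res$strengths$strengths, "strengths.tsv")
    wt(res$strengths$roles, "roles.tsv")
  }
  jsonlite::write_json(
    list(params = res$params, k = res$k,
         start_cluster = res$trajectory$start_cluster,
         cluster_order = res$trajectory$cluster_order,
         edge_weights = res$trajectory$edge_weights),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
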