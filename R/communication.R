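# Cluster-level ligand-receptor communication: Hill-transformed cluster mean
# ligand x receptor expression, permutation significance, strengths and roles.

# Library-size normalize each cell to the median library size, then log1p.
normalize_counts <- function(m) {
  lib <- colSums(m)
  lib[lib == 0] <- 1
  log1p(t(t(m) * (stats::median(colSums(m)) / lib)))
}

# Cluster-average expression of the genes in `genes` (rows) per cluster.
cluster_means <- function(norm, labels, clusters) {
  vapply(clusters, function(k) rowMeans(norm[, labels == k, drop = FALSE]),
         numeric(nrow(norm)))
}

# Drop database entries with missing subunit genes (with a warning).
prune_db <- function(db, genes) {
  ok <- vapply(seq_len(nrow(db)), function(i) {
    all(c(split_subunits(db$ligand[i]), split_subunits(db$receptor[i]))
        %in% genes)
  }, logical(1))
  if (!any(ok)) stop("no ligand-receptor pair has all subunits in the matrix")
  if (any(!ok))
    warning(sum(!ok), " ligand-receptor pair(s) dropped: missing subunit genes")
  db[ok, , drop = FALSE]
}

# prob array (sender x receiver x pair) from cluster-mean expression.
prob_from_means <- function(mu, db, Kh) {
  clusters <- colnames(mu)
  npair <- nrow(db)
  pair_id <- paste0(db$pathway, ":", db$ligand, "->", db$receptor)
  prob <- array(0, dim = c(length(clusters), length(clusters), npair),
                dimnames = list(clusters, clusters, pair_id))
  for (p in seq_len(npair)) {
    L <- apply(mu[split_subunits(db$ligand[p]), , drop = FALSE], 2, geom_mean)
    R <- apply(mu[split_subunits(db$receptor[p]), , drop = FALSE], 2, geom_mean)
    LR <- outer(L, R)
    prob[, , p] <- LR / (Kh + LR)
  }
  prob
}

#' Cluster-to-cluster communication probabilities
#'
#' Raw counts are library-size normalized per cell (to the median library
#' size) and log1p-transformed. For each ligand-receptor pair, the ligand
#' level of a sender cluster is the geometric mean over ligand subunits of
#' the cluster-average expression (a zero subunit nullifies the complex);
#' receptor levels likewise for receivers. The communication probability is
#' the Hill saturation `L * R / (Kh + L * R)`, in [0, 1] and monotone
#' nondecreasing in both L and R.
#'
#' @param raw A [count_matrix()] or named matrix of raw counts.
#' @param labels Per-cell cluster labels.
#' @param db An [lr_database()]; pairs whose subunit genes are missing from
#'   the matrix are dropped with a warning.
#' @param Kh Hill constant (> 0) on the normalized-log scale (default 0.5).
#' @return A list of class `communication` with `prob` (sender x receiver x
#'   pair array), `pathway_of_pair`, `clusters`, `Kh`, and `pvals = NULL`
#'   (see [permutation_significance()]).
#' @export
communication_probability <- function(raw, labels, db, Kh = 0.5) {
  m <- as_count_values(raw)
  if (length(labels) != ncol(m)) stop("labels must cover all cells")
  if (Kh <= 0) stop("Kh must be positive")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  db <- prune_db(db, rownames(m))
  genes <- unique(unlist(lapply(seq_len(nrow(db)), function(i)
    c(split_subunits(db$ligand[i]), split_subunits(db$receptor[i])))))
  norm <- normalize_counts(m)[genes, , drop = FALSE]
  mu <- cluster_means(norm, labels, clusters)
  colnames(mu) <- as.character(clusters)
  prob <- prob_from_means(mu, db, Kh)
  structure(list(prob = prob,
                 pathway_of_pair = stats::setNames(db$pathway,
                                                   dimnames(prob)[[3]]),
                 clusters = clusters, Kh = Kh, nperm = 0L, pvals = NULL),
            class = "communication")
}

#' Permutation significance of communication probabilities
#'
#' Null distribution by global permutation of the cluster labels: for each
#' replicate all labels are shuffled and the probability tensor recomputed.
#' The p-value of each (sender, receiver, pair) entry is
#' `(1 + #(permuted >= observed)) / (1 + nperm)`.
#'
#' @inheritParams communication_probability
#' @param nperm Number of label permutations (default 100).
#' @param seed Integer seed.
#' @return The `communication` object with `pvals` (same shape as `prob`)
#'   and `nperm` filled in.
#' @export
permutation_significance <- function(raw, labels, db, Kh = 0.5,
                                     nperm = 100, seed = 1L) {
  if (nperm < 1) stop("nperm must be >= 1")
  comm <- suppressWarnings(communication_probability(raw, labels, db, Kh))
  m <- as_count_values(raw)
  db <- suppressWarnings(prune_db(db, rownames(m)))
  genes <- unique(unlist(lapply(seq_len(nrow(db)), function(i)
    c(split_subunits(db$ligand[i]), split_subunits(db$receptor[i])))))
  norm <- normalize_counts(m)[genes, , drop = FALSE]
  clusters <- comm$clusters
  exceed <- array(0L, dim = dim(comm$prob))
  with_seed(seed, {
    for (r in seq_len(nperm)) {
      perm <- sample(labels)
      mu <- cluster_means(norm, perm, clusters)
      colnames(mu) <- as.character(clusters)
      pp <- prob_from_means(mu, db, Kh)
      exceed <- exceed + (pp >= comm$prob)
    }
  })
  comm$pvals <- (1 + exceed) / (1 + nperm)
  dimnames(comm$pvals) <- dimnames(comm$prob)
  comm$nperm <- as.integer(nperm)
  comm
}

# Zero out non-significant entries; prob tensor with pvals applied.
significant_prob <- function(comm, alpha) {
  prob <- comm$prob
  if (!is.null(comm$pvals)) prob[comm$pvals >= alpha] <- 0
  prob
}

#' Outgoing/incoming interaction strengths and signaling roles
#'
#' Pairs with permutation p-value >= `alpha` are zeroed (when p-values are
#' present). The outgoing strength of a cluster is the sum of its
#' probabilities as a sender over all receivers and pairs; incoming likewise
#' as a receiver. Per pathway, a cluster's sender score is its row sum of
#' the pathway's aggregated probability matrix, the receiver score the
#' column sum, the influencer score their total, and the mediator score the
#' cluster's flow betweenness in the pathway's weighted directed graph
#' (total max-flow between other cluster pairs lost when the cluster is
#' removed).
#'
#' @param comm A `communication` object (with p-values for filtering).
#' @param alpha Significance threshold (default 0.05).
#' @return A list with `strengths` (`data.frame`: cluster, outgoing,
#'   incoming) and `roles` (`data.frame`: pathway, cluster, sender,
#'   receiver, mediator, influencer).
#' @export
interaction_strengths <- function(comm, alpha = 0.05) {
  prob <- significant_prob(comm, alpha)
  k <- length(comm$clusters)
  out_total <- apply(prob, 1, sum)
  in_total <- apply(prob, 2, sum)
  strengths <- data.frame(cluster = comm$clusters,
                          outgoing = as.numeric(out_total),
                          incoming = as.numeric(in_total))
  pathways <- unique(comm$pathway_of_pair)
  roles <- do.call(rbind, lapply(pathways, function(pw) {
    idx <- which(comm$pathway_of_pair == pw)
    P <- apply(prob[, , idx, drop = FALSE], c(1, 2), sum)
    snd <- rowSums(P)
    rcv <- colSums(P)
    data.frame(pathway = pw, cluster = comm$clusters,
               sender = as.numeric(snd), receiver = as.numeric(rcv),
               mediator = flow_betweenness(P),
               influencer = as.numeric(snd + rcv))
  }))
  rownames(roles) <- NULL
  list(strengths = strengths, roles = roles)
}

# Flow betweenness of each node in a weighted digraph given as a k x k
# capacity matrix: sum over ordered pairs (s, t) of the max-flow reduction
# when the node is removed.
flow_betweenness <- function(P) {
  k <- nrow(P)
  diag(P) <- 0
  if (all(P == 0)) return(rep(0, k))
  g <- igraph::graph_from_adjacency_matrix(P, mode = "directed",
                                           weighted = TRUE)
  mf <- function(graph, s, t) {
    igraph::max_flow(graph, s, t,
                     capacity = igraph::E(graph)$weight)$value
  }
  base <- matrix(0, k, k)
  for (s in seq_len(k)) for (t in seq_len(k)) {
    if (s != t) base[s, t] <- mf(g, s, t)
  }
  vapply(seq_len(k), function(v) {
    gv <- igraph::delete_vertices(g, v)
    tot <- 0
    keep <- setdiff(seq_len(k), v)
    for (si in seq_along(keep)) for (ti in seq_along(keep)) {
      s <- keep[si]; t <- keep[ti]
      if (s != t && base[s, t] > 0)
        tot <- tot + (base[s, t] - mf(gv, si, ti))
    }
    tot
  }, numeric(1))
}

#' Per-pathway information flow
#'
#' Total communication probability of a pathway: the sum over all
#' significant (sender, receiver, pair) entries belonging to it.
#'
#' @inheritParams interaction_strengths
#' @return Named numeric vector, one entry per pathway.
#' @export
information_flow <- function(comm, alpha = 0.05) {
  prob <- significant_prob(comm, alpha)
  pathways <- unique(comm$pathway_of_pair)
  vapply(stats::setNames(pathways, pathways), function(pw) {
    sum(prob[, , comm$pathway_of_pair == pw, drop = FALSE])
  }, numeric(1))
}

#' Compare pathway information flow across conditions
#'
#' @param comms Named list of `communication` objects (one per condition)
#'   computed against databases sharing pathways; disjoint pathway sets are
#'   an error.
#' @param alpha Significance threshold.
#' @return `data.frame` with one row per (pathway, condition): absolute
#'   `flow`, `rel_flow` (flow / condition total; 0 when the condition total
#'   is 0) and `exclusive` (pathway has nonzero flow only in this
#'   condition).
#' @export
compare_conditions <- function(comms, alpha = 0.05) {
  if (is.null(names(comms)) || any(!nzchar(names(comms))))
    stop("comms must be a named list of conditions")
  flows <- lapply(comms, information_flow, alpha = alpha)
  pw_sets <- lapply(flows, names)
  if (length(Reduce(intersect, pw_sets)) == 0)
    stop("conditions have disjoint pathway sets")
  pathways <- Reduce(union, pw_sets)
  tab <- do.call(rbind, lapply(names(comms), function(cond) {
    f <- flows[[cond]][pathways]
    f[is.na(f)] <- 0
    tot <- sum(f)
    data.frame(pathway = pathways, condition = cond, flow = as.numeric(f),
               rel_flow = if (tot > 0) as.numeric(f) / tot else 0)
  }))
  nz <- tapply(tab$flow > 0, tab$pathway, sum)
  tab$exclusive <- tab$flow > 0 & nz[tab$pathway] == 1
  rownames(tab) <- NULL
  tab
}
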