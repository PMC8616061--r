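#' Signature-anchored trajectory over soft clusters
#'
#' The starting cluster is the one with the highest epithelial and lowest
#' mesenchymal mean score, formalized as the minimal rank-sum of (rank of E
#' score, descending) + (rank of M score, ascending); an unresolvable tie is
#' an error listing the tied clusters (in that case different starting
#' clusters should be tested explicitly). Edges between clusters are
#' weighted by the number of transition cells whose two largest memberships
#' are that cluster pair; the trajectory is the maximum-weight simple path
#' from the start (exhaustive search for k <= `exhaustive_max`, greedy
#' heaviest-next-edge beyond). Pseudotime places each cell at the position of
#' its hard cluster in the trajectory order, shifted toward the adjacent
#' cluster with which it shares the most membership:
#' `position(a) + h_b / (h_a + h_b)` where `a` is the hard cluster and `b`
#' its adjacent cluster in the order with the larger membership (terminal
#' clusters use their single neighbor). The shift is forward when the
#' neighbor lies later on the path and backward when it lies earlier, so
#' pseudotime stays within `[0, k - 1]`.
#'
#' @param membership A `soft_membership` from [soft_cluster()].
#' @param cluster_scores `data.frame` with columns `cluster`, `E_mean`,
#'   `M_mean` (as produced by [summarize_by_cluster()] on [score_emt()]
#'   output) for every cluster.
#' @param exhaustive_max Largest k for which all simple paths are enumerated
#'   (default 6).
#' @return A list of class `emt_trajectory`: `start_cluster`,
#'   `cluster_order`, `edge_weights` (symmetric k x k transition-cell count
#'   matrix), `alt_paths` (other maximal simple paths from the start, by
#'   descending total weight), `pseudotime` (per cell, in [0, k - 1]).
#' @export
infer_trajectory <- function(membership, cluster_scores,
                             exhaustive_max = 6) {
  H <- membership$H
  k <- ncol(H)
  if (k < 2) stop("need at least 2 clusters")
  cs <- cluster_scores
  if (!all(c("cluster", "E_mean", "M_mean") %in% names(cs)))
    stop("cluster_scores needs columns cluster, E_mean, M_mean")
  cs <- cs[match(seq_len(k), cs$cluster), ]
  if (any(is.na(cs$E_mean)))
    stop("cluster_scores must cover every cluster 1..k")

  rank_sum <- rank(-cs$E_mean, ties.method = "min") +
    rank(cs$M_mean, ties.method = "min")
  best <- which(rank_sum == min(rank_sum))
  if (length(best) > 1)
    stop("starting cluster unresolved; tied clusters: ",
         paste(best, collapse = ", "),
         " (test each as an explicit starting point)")
  start <- best[1]

  # transition-cell counts per unordered top-2 cluster pair
  W <- matrix(0, k, k)
  trans <- which(membership$transition_flag)
  for (c in trans) {
    top2 <- order(H[c, ], decreasing = TRUE)[1:2]
    a <- min(top2); b <- max(top2)
    W[a, b] <- W[a, b] + 1
    W[b, a] <- W[a, b]
  }

  # EMT axis (mesenchymal minus epithelial mean score) orders clusters that
  # transition-cell edges leave unresolved (e.g. no transition cells at all)
  em_axis <- cs$M_mean - cs$E_mean
  paths <- enumerate_paths(W, start, em_axis,
                           exhaustive = k <= exhaustive_max)
  order_main <- paths$main
  alt <- paths$alt

  pos <- match(seq_len(k), order_main)   # position of each cluster, 1-based
  hard <- membership$hard_label
  pt <- vapply(seq_len(nrow(H)), function(c) {
    a <- hard[c]
    p <- pos[a]
    if (is.na(p)) return(NA_real_)       # cluster not on the main path
    nbr <- c(if (p > 1) order_main[p - 1], if (p < k) order_main[p + 1])
    b <- nbr[which.max(H[c, nbr])]
    shift <- H[c, b] / (H[c, a] + H[c, b])
    # shift toward the neighbor: forward if b lies later on the path,
    # backward if earlier, keeping pseudotime within [0, k - 1]
    (p - 1) + if (pos[b] > p) shift else -shift
  }, numeric(1))
  names(pt) <- rownames(H)

  structure(list(start_cluster = start, cluster_order = order_main,
                 edge_weights = W, alt_paths = alt, pseudotime = pt),
            class = "emt_trajectory")
}

# Maximum-weight simple paths from `start` in the weighted graph W.
# Exhaustive: enumerate all maximal simple paths, order by total weight
# (ties: longer first). Greedy: heaviest next edge. Clusters unreachable
# through positive-weight edges are appended along `em_axis`, ascending.
enumerate_paths <- function(W, start, em_axis, exhaustive = TRUE) {
  k <- nrow(W)
  if (exhaustive) {
    all_paths <- list()
    grow <- function(path) {
      last <- path[length(path)]
      nxt <- setdiff(which(W[last, ] > 0), path)
      if (length(nxt) == 0) {
        all_paths[[length(all_paths) + 1]] <<- path
      } else {
        for (v in nxt) grow(c(path, v))
      }
    }
    grow(start)
    wt <- vapply(all_paths, function(p) {
      if (length(p) < 2) return(0)
      sum(W[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    len <- lengths(all_paths)
    ord <- order(-wt, -len)
    all_paths <- all_paths[ord]
    main <- all_paths[[1]]
    alt <- all_paths[-1]
  } else {
    main <- start
    repeat {
      last <- main[length(main)]
      cand <- setdiff(which(W[last, ] > 0), main)
      if (length(cand) == 0) break
      main <- c(main, cand[which.max(W[last, cand])])
    }
    alt <- list()
  }
  # the order must cover all clusters: disconnected ones follow the EMT axis
  missing <- setdiff(seq_len(k), main)
  if (length(missing))
    main <- c(main, missing[order(em_axis[missing])])
  list(main = main, alt = alt)
}
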