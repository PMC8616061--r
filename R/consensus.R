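#' Consensus cell-cell similarity from a PCA + k-means ensemble
#'
#' Runs k-means `n_runs` times on PCA embeddings of the cells, cycling over a
#' grid of principal-component counts and over candidate cluster numbers
#' `k_range`, each run from a fresh random start. The consensus similarity of
#' two cells is the fraction of runs that co-cluster them; the diagonal is 1.
#' Eigenvalues of the similarity matrix (descending) are returned for
#' eigengap model selection.
#'
#' @param expr Numeric genes x cells matrix (log expression).
#' @param n_runs Number of base clusterings (default 50).
#' @param k_range Candidate cluster counts swept by the ensemble (default
#'   3:6).
#' @param pc_grid Principal-component counts swept (default c(5, 10, 15),
#'   capped by the data dimensions).
#' @param seed Integer seed; results are deterministic given it.
#' @return A list of class `consensus_result`: `similarity` (cells x cells,
#'   in [0, 1], symmetric, unit diagonal), `eigenvalues` (descending),
#'   `runs`.
#' @export
build_consensus <- function(expr, n_runs = 50, k_range = 3:6,
                            pc_grid = c(5, 10, 15), seed = 1L) {
  n_cells <- ncol(expr)
  if (n_cells < 2) stop("need at least 2 cells")
  if (n_runs < 1) stop("n_runs must be >= 1")
  k_range <- k_range[k_range < n_cells & k_range >= 2]
  if (length(k_range) == 0) stop("no valid k in k_range")
  max_pc <- min(nrow(expr), n_cells - 1)
  pc_grid <- unique(pmin(pc_grid, max_pc))
  with_seed(seed, {
    pca <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE,
                         rank. = max(pc_grid))
    # canonicalize PC signs (largest-|loading| gene positive) so the
    # embedding, and hence the whole ensemble, is invariant to cell order
    flip <- apply(pca$rotation, 2, function(v) sign(v[which.max(abs(v))]))
    scores <- sweep(pca$x, 2, flip, "*")
    combos <- expand.grid(k = k_range, npc = pc_grid)
    co <- matrix(0, n_cells, n_cells)
    for (r in seq_len(n_runs)) {
      cb <- combos[((r - 1) %% nrow(combos)) + 1, ]
      emb <- scores[, seq_len(cb$npc), drop = FALSE]
      # run-specific random projection; initial centers at its quantiles.
      # Value-based (not index-based), so permuting cells permutes results.
      u <- stats::rnorm(cb$npc)
      proj <- as.numeric(emb %*% u)
      ord <- order(proj)
      ctr_idx <- ord[ceiling((seq_len(cb$k) - 0.5) / cb$k * n_cells)]
      ctr <- emb[ctr_idx, , drop = FALSE]
      # nudge coincident centers apart (duplicated cells) deterministically
      if (anyDuplicated(ctr))
        ctr <- ctr + seq_len(cb$k) * 1e-9 * max(abs(ctr), 1)
      cl <- tryCatch(
        stats::kmeans(emb, centers = ctr, iter.max = 100)$cluster,
        error = function(e)
          stats::kmeans(emb, centers = ctr, iter.max = 100,
                        algorithm = "Lloyd")$cluster)
      same <- outer(cl, cl, "==")
      co <- co + same
    }
    S <- co / n_runs
    diag(S) <- 1
    dimnames(S) <- list(colnames(expr), colnames(expr))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    structure(list(similarity = S,
                   eigenvalues = sort(ev, decreasing = TRUE),
                   runs = n_runs),
              class = "consensus_result")
  })
}

#' Select the number of clusters by the maximal eigengap
#'
#' Returns the k in `[k_min, k_max]` maximizing the gap between consecutive
#' eigenvalues of the consensus similarity matrix (sorted descending). The
#' floor `k_min = 3` guarantees at least one candidate intermediate state
#' between the epithelial and mesenchymal extremes. Ties go to the smallest
#' k.
#'
#' @param cons A `consensus_result` (or a list with an `eigenvalues` field).
#' @param k_min Minimum cluster count (default 3).
#' @param k_max Maximum cluster count considered.
#' @return The selected integer k.
#' @export
select_k <- function(cons, k_min = 3, k_max = 8) {
  ev <- cons$eigenvalues
  if (k_min < 2) stop("k_min must be >= 2")
  if (k_max >= length(ev)) stop("k_max must be smaller than the cell count")
  if (k_max < k_min) stop("k_max must be >= k_min")
  ks <- k_min:k_max
  gaps <- ev[ks] - ev[ks + 1]
  # ties (within numerical noise) resolve to the smallest k
  ks[which(gaps >= max(gaps) - 1e-9)[1]]
}

#' Soft clustering of the consensus similarity by symmetric NMF
#'
#' Finds a nonnegative cells x k matrix H minimizing ||S - H H'||_F by
#' multiplicative updates from a seeded random initialization, stopping when
#' the relative objective change drops below `tol` or after `max_iter`
#' iterations (a warning is issued on non-convergence and the best iterate
#' returned). Rows of H are then normalized to sum to 1 and read as soft
#' cluster memberships. A cell is flagged as a transition cell when the gap
#' between its largest and second-largest membership is below `delta`.
#'
#' @param cons A `consensus_result`.
#' @param k Number of clusters.
#' @param delta Transition gap threshold (default 0.1).
#' @param seed Integer seed for the initialization.
#' @param n_restarts Number of random initializations; the factorization
#'   with the lowest final objective is kept (default 5).
#' @param max_iter,tol Iteration cap and relative-objective tolerance.
#' @return A list of class `soft_membership`: `H` (row-stochastic cells x k),
#'   `hard_label` (argmax cluster per cell), `transition_flag` (logical),
#'   `delta`, `objective` (final value of ||S - HH'||_F^2 before row
#'   normalization).
#' @export
soft_cluster <- function(cons, k, delta = 0.1, seed = 1L, n_restarts = 5,
                         max_iter = 500, tol = 1e-6) {
  S <- cons$similarity
  n <- nrow(S)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < number of cells")
  eps <- 1e-12
  normS2 <- norm(S, "F")^2
  with_seed(seed, {
    best <- NULL
    any_converged <- FALSE
    for (rs in seq_len(n_restarts)) {
      H <- matrix(stats::runif(n * k, 0.1, 1), n, k) * sqrt(mean(S) / k)
      obj_old <- Inf
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        HtH <- crossprod(H)
        H <- H * (S %*% H) / pmax(H %*% HtH, eps)
        obj <- norm(S - tcrossprod(H), "F")^2
        # stop on small relative change, or on an essentially exact fit
        # (relative change never triggers when the optimum is exactly zero)
        if (obj <= tol * normS2 ||
            (is.finite(obj_old) &&
             abs(obj_old - obj) <= tol * max(obj_old, eps))) {
          converged <- TRUE
          break
        }
        obj_old <- obj
      }
      any_converged <- any_converged || converged
      if (is.null(best) || obj < best$obj) best <- list(H = H, obj = obj)
    }
    if (!any_converged)
      warning("symmetric NMF did not converge in ", max_iter,
              " iterations in any restart; returning best iterate")
    H <- best$H
    obj <- best$obj
    Hn <- H / pmax(rowSums(H), eps)
    hard <- max.col(Hn, ties.method = "first")
    sorted <- t(apply(Hn, 1, sort, decreasing = TRUE))
    gap <- sorted[, 1] - sorted[, 2]
    rownames(Hn) <- rownames(S)
    structure(list(H = Hn, hard_label = hard,
                   transition_flag = gap < delta, delta = delta,
                   objective = obj),
              class = "soft_membership")
  })
}

# Remove clusters that attract no hard-assigned cell (vacuous components of
# the factorization), renormalize memberships and recompute labels/flags.
drop_empty_clusters <- function(memb) {
  used <- sort(unique(memb$hard_label))
  if (length(used) == ncol(memb$H)) return(memb)
  H <- memb$H[, used, drop = FALSE]
  H <- H / pmax(rowSums(H), 1e-12)
  hard <- max.col(H, ties.method = "first")
  sorted <- t(apply(H, 1, sort, decreasing = TRUE))
  gap <- if (ncol(H) >= 2) sorted[, 1] - sorted[, 2] else rep(1, nrow(H))
  memb$H <- H
  memb$hard_label <- hard
  memb$transition_flag <- gap < memb$delta
  memb
}
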