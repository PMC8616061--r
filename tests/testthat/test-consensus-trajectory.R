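# Block-constant similarity matrix with perfect blocks of the given sizes.
block_similarity <- function(sizes) {
  n <- sum(sizes)
  S <- matrix(0, n, n, dimnames = list(paste0("c", 1:n), paste0("c", 1:n)))
  start <- cumsum(c(1, sizes))
  for (b in seq_along(sizes)) {
    idx <- start[b]:(start[b] + sizes[b] - 1)
    S[idx, idx] <- 1
  }
  S
}

as_consensus <- function(S) {
  structure(list(similarity = S,
                 eigenvalues = sort(eigen(S, symmetric = TRUE,
                                          only.values = TRUE)$values,
                                    decreasing = TRUE),
                 runs = 1L), class = "consensus_result")
}

test_that("near-identical cell groups co-cluster; similarity is equivariant", {
  set.seed(12)
  grp <- matrix(rep(c(0, 5), each = 20 * 6), nrow = 20)  # two tight groups
  rownames(grp) <- paste0("g", 1:20)
  colnames(grp) <- paste0("c", 1:12)
  grp <- grp + matrix(rnorm(20 * 12, sd = 0.01), nrow = 20)
  cons <- build_consensus(grp, n_runs = 20, k_range = 2, seed = 1)
  S <- cons$similarity
  within <- c(S[1:6, 1:6], S[7:12, 7:12])
  between <- S[1:6, 7:12]
  expect_true(all(within == 1))
  expect_lt(mean(between), min(within))
  expect_equal(S, t(S))
  expect_true(all(diag(S) == 1))
  expect_true(all(S >= 0 & S <= 1))

  perm <- c(4, 1, 12, 7, 3, 9, 2, 11, 6, 10, 5, 8)
  cons_p <- build_consensus(grp[, perm], n_runs = 20, k_range = 2, seed = 1)
  expect_equal(cons_p$similarity, cons$similarity[perm, perm])
})

test_that("eigengap selection recovers block counts, with a floor of three", {
  expect_equal(select_k(as_consensus(block_similarity(c(3, 3, 3))),
                        k_min = 3, k_max = 6), 3)
  expect_equal(select_k(as_consensus(block_similarity(c(4, 4, 4, 4))),
                        k_min = 3, k_max = 8), 4)
  # two blocks but constrained floor -> smallest allowed k
  expect_equal(select_k(as_consensus(block_similarity(c(5, 5))),
                        k_min = 3, k_max = 6), 3)
  ev <- as_consensus(block_similarity(c(3, 3, 3)))$eigenvalues
  expect_equal(ev[1:4], c(3, 3, 3, 0))
  cons <- as_consensus(block_similarity(c(3, 3)))
  expect_error(select_k(cons, k_min = 3, k_max = 6), "cell count")
  expect_error(select_k(cons, k_min = 1, k_max = 3), "k_min")
})

test_that("symmetric NMF recovers perfect blocks with no transition cells", {
  S <- block_similarity(c(5, 4, 6))
  memb <- suppressWarnings(soft_cluster(as_consensus(S), k = 3, seed = 3))
  truth <- rep(1:3, c(5, 4, 6))
  expect_equal(ari(memb$hard_label, truth), 1)
  expect_equal(sum(memb$transition_flag), 0)
  expect_equal(rowSums(memb$H), rep(1, 15), ignore_attr = TRUE)
})

test_that("transition flags follow the membership-gap rule", {
  S <- block_similarity(c(4, 4, 4))
  memb <- suppressWarnings(soft_cluster(as_consensus(S), k = 3, seed = 1))
  # inject known membership rows to check the flag rule directly
  memb$H[1, ] <- c(0.5, 0.5, 0)
  memb$H[2, ] <- c(0.9, 0.1, 0)
  gap <- apply(memb$H, 1, function(h) {
    s <- sort(h, decreasing = TRUE); s[1] - s[2]
  })
  expect_true(gap[1] < 0.1)   # flagged at delta = 0.1
  expect_false(gap[2] < 0.1)
})

test_that("trajectory starts at the most epithelial cluster and follows edges", {
  # hand-built membership: 3 clusters, transition cells on {1,2} x10, {2,3} x7,
  # {1,3} x1
  k <- 3
  rows <- list()
  add <- function(h, times) for (i in seq_len(times))
    rows[[length(rows) + 1]] <<- h
  add(c(0.96, 0.03, 0.01), 5)   # hard cluster 1
  add(c(0.02, 0.96, 0.02), 5)   # hard cluster 2
  add(c(0.01, 0.03, 0.96), 5)   # hard cluster 3
  add(c(0.49, 0.47, 0.04), 10)  # transition {1,2}
  add(c(0.04, 0.49, 0.47), 7)   # transition {2,3}
  add(c(0.49, 0.04, 0.47), 1)   # transition {1,3}
  H <- do.call(rbind, rows)
  rownames(H) <- paste0("c", seq_len(nrow(H)))
  memb <- structure(list(H = H,
                         hard_label = max.col(H, ties.method = "first"),
                         transition_flag = apply(H, 1, function(h) {
                           s <- sort(h, decreasing = TRUE); s[1] - s[2] < 0.1
                         }),
                         delta = 0.1), class = "soft_membership")
  cs <- data.frame(cluster = 1:3, E_mean = c(0.8, 0.5, 0.2),
                   M_mean = c(0.1, 0.4, 0.7))
  traj <- infer_trajectory(memb, cs)
  expect_equal(traj$start_cluster, 1)
  expect_equal(traj$cluster_order, c(1, 2, 3))
  expect_equal(traj$edge_weights[1, 2], 10)
  expect_equal(traj$edge_weights[2, 3], 7)
  expect_equal(traj$edge_weights[1, 3], 1)
  # alternative maximal path 1 -> 3 -> 2 has lower total weight
  expect_equal(traj$alt_paths[[1]], c(1, 3, 2))
})

test_that("pseudotime interpolates between adjacent clusters as specified", {
  H <- rbind(c(0.6, 0.4, 0), c(0.1, 0.8, 0.1), c(0, 0.2, 0.8))
  rownames(H) <- paste0("c", 1:3)
  memb <- structure(list(H = H, hard_label = c(1L, 2L, 3L),
                         transition_flag = rep(FALSE, 3), delta = 0.1),
                    class = "soft_membership")
  cs <- data.frame(cluster = 1:3, E_mean = c(0.9, 0.5, 0.1),
                   M_mean = c(0.1, 0.5, 0.9))
  traj <- infer_trajectory(memb, cs)
  expect_equal(traj$cluster_order, c(1, 2, 3))
  # cell 1: position 0 shifted forward toward cluster 2: 0 + 0.4 / (0.6 + 0.4)
  expect_equal(unname(traj$pseudotime[1]), 0.4)
  # cell 2: equal neighbors -> which.max takes the earlier; 1 - 0.1/0.9
  expect_equal(unname(traj$pseudotime[2]), 1 - 0.1 / 0.9)
  # cell 3: terminal cluster, single (earlier) neighbor 2: 2 - 0.2/1.0
  expect_equal(unname(traj$pseudotime[3]), 2 - 0.2 / 1.0)
  expect_true(all(traj$pseudotime >= 0 & traj$pseudotime <= 2))
})

test_that("an unresolvable start tie is an explicit error", {
  H <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  rownames(H) <- c("a", "b")
  memb <- structure(list(H = H, hard_label = c(1L, 2L),
                         transition_flag = c(FALSE, FALSE), delta = 0.1),
                    class = "soft_membership")
  cs <- data.frame(cluster = 1:2, E_mean = c(0.5, 0.5), M_mean = c(0.3, 0.3))
  expect_error(infer_trajectory(memb, cs), "tied clusters")
})

test_that("clusters unlinked by transition cells are ordered along the EMT axis", {
  H <- diag(4)[rep(1:4, each = 3), ]
  rownames(H) <- paste0("c", 1:12)
  memb <- structure(list(H = H, hard_label = rep(1:4, each = 3),
                         transition_flag = rep(FALSE, 12), delta = 0.1),
                    class = "soft_membership")
  cs <- data.frame(cluster = 1:4, E_mean = c(0.3, 0.9, 0.5, 0.1),
                   M_mean = c(0.6, 0.1, 0.4, 0.8))
  traj <- infer_trajectory(memb, cs)
  expect_equal(traj$start_cluster, 2)
  expect_equal(traj$cluster_order, c(2, 3, 1, 4))
})
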