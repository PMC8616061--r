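test_that("transcriptional diversity counts expressed genes per cell", {
  m <- toy_counts(c(0, 3, 1, 0), genes = paste0("g", 1:4), cells = "c1")
  expect_equal(unname(transcriptional_diversity(m)), 2)
  m0 <- toy_counts(rep(0, 4), genes = paste0("g", 1:4), cells = "c1")
  expect_equal(unname(transcriptional_diversity(m0)), 0)

  set.seed(5)
  big <- toy_counts(rpois(200 * 50, 0.8), genes = paste0("g", 1:200),
                    cells = paste0("c", 1:50))
  brute <- vapply(seq_len(50), function(c) sum(big[, c] != 0), numeric(1))
  expect_equal(unname(transcriptional_diversity(big)), brute)
})

test_that("gene network thresholds absolute correlation at tau", {
  set.seed(11)
  base <- rnorm(30)
  expr <- rbind(a = base, b = base, c = rnorm(30), d = -base)
  colnames(expr) <- paste0("c", 1:30)
  net <- build_gene_network(expr, tau = 1.0)
  expect_true(net$adjacency["a", "b"])     # duplicated rows: corr exactly 1
  expect_true(net$adjacency["a", "d"])     # |corr| = 1 (anti-correlated)
  expect_false(net$adjacency["a", "c"])
  expect_false(any(diag(net$adjacency)))
  expect_equal(net$adjacency, t(net$adjacency))

  flat <- rbind(expr, e = rep(2, 30))      # zero variance -> isolated
  net2 <- build_gene_network(flat, tau = 0.4)
  expect_false(any(net2$adjacency["e", ]))
  expect_error(build_gene_network(expr, tau = 0), "tau")
  expect_error(build_gene_network(expr, tau = 1.5), "tau")
})

test_that("independent genes rarely pass tau = 0.4 at n = 500", {
  set.seed(23)
  hits <- vapply(1:100, function(i) {
    expr <- rbind(x = rnorm(500), y = rnorm(500))
    colnames(expr) <- paste0("c", 1:500)
    build_gene_network(expr, tau = 0.4)$adjacency["x", "y"]
  }, logical(1))
  expect_lte(mean(hits), 0.01)
})

test_that("single-cell energy matches the closed form on small networks", {
  # triangle, all z = 1: each term -1 * ln(1/2) = ln 2
  expr <- matrix(c(1, 1, 1), 3, 1, dimnames = list(c("a", "b", "c"), "cell"))
  A <- matrix(TRUE, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(A) <- FALSE
  net <- structure(list(genes = c("a", "b", "c"), adjacency = A, tau = 0.4,
                        method = "pearson"), class = "gene_network")
  expect_equal(unname(single_cell_energy(expr, net)), 3 * log(2))

  # all-zero cell -> 0; isolated gene contributes nothing
  expr2 <- matrix(c(1, 1, 1, 0, 0, 0), 3, 2,
                  dimnames = list(c("a", "b", "c"), c("hot", "cold")))
  expect_equal(unname(single_cell_energy(expr2, net)[["cold"]]), 0)
  A_iso <- A; A_iso["c", ] <- FALSE; A_iso[, "c"] <- FALSE
  net_iso <- structure(list(genes = c("a", "b", "c"), adjacency = A_iso,
                            tau = 0.4, method = "pearson"),
                       class = "gene_network")
  # pair a-b with z = 1: each term -ln(1/1) = 0; c isolated
  expect_equal(unname(single_cell_energy(expr2, net_iso)[["hot"]]), 0)

  expect_error(single_cell_energy(expr2[1:2, ], net), "absent")
})

test_that("energy is invariant to gene and cell permutations", {
  ds <- generate_emt_dataset(small_config(seed = 14, cells = 25L))
  pp <- preprocess(ds$counts, top_n_genes = 120, min_gene_fraction = 0.02)
  net <- build_gene_network(pp$expr, tau = 0.4)
  en <- single_cell_energy(pp$expr, net)
  pg <- sample(nrow(pp$expr)); pc <- sample(ncol(pp$expr))
  expr_p <- pp$expr[pg, pc]
  net_p <- build_gene_network(expr_p, tau = 0.4)
  en_p <- single_cell_energy(expr_p, net_p)
  expect_equal(en_p[names(en)], en)
})

test_that("EMT circuit energy equals restriction to signature genes only", {
  ds <- generate_emt_dataset(small_config(seed = 6, cells = 20L))
  pp <- preprocess(ds$counts, top_n_genes = 150, min_gene_fraction = 0.02)
  sig_e <- ds$signatures$epithelial
  sig_m <- ds$signatures$mesenchymal
  e1 <- emt_circuit_energy(pp$expr, sig_e, sig_m, tau = 0.4)

  # definitional equivalence on a signature-only matrix
  sub <- pp$expr[intersect(rownames(pp$expr), c(sig_e, sig_m)), ]
  net <- build_gene_network(sub, tau = 0.4)
  expect_equal(e1, single_cell_energy(sub, net))

  # perturbing non-signature genes leaves the energy bit-identical
  expr2 <- pp$expr
  hk <- setdiff(rownames(expr2), c(sig_e, sig_m))
  expr2[hk, ] <- expr2[hk, sample(ncol(expr2))] * 3 + 1
  expect_identical(e1, emt_circuit_energy(expr2, sig_e, sig_m, tau = 0.4))

  expect_error(emt_circuit_energy(pp$expr, "nope1", "nope2", tau = 0.4),
               "fewer than 2")
})

test_that("co-expressing cells carry more circuit energy than one-program cells", {
  # two blocks of correlated genes (E and M programs); cells either express
  # both programs or only M at the same total output
  set.seed(33)
  n_cells <- 60
  e_levels <- c(rep(4, 30), rep(0.5, 30))   # co-expressors first
  m_levels <- c(rep(4, 30), rep(7.5, 30))
  expr <- rbind(
    t(vapply(1:10, function(i) e_levels + rnorm(n_cells, sd = 0.3),
             numeric(n_cells))),
    t(vapply(1:10, function(i) m_levels + rnorm(n_cells, sd = 0.3),
             numeric(n_cells))))
  rownames(expr) <- c(paste0("E", 1:10), paste0("M", 1:10))
  colnames(expr) <- paste0("c", 1:n_cells)
  en <- emt_circuit_energy(expr, paste0("E", 1:10), paste0("M", 1:10),
                           tau = 0.4)
  expect_gt(mean(en[1:30]), mean(en[31:60]))
})
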