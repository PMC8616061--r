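# Build a communication object directly from a prob array (bypassing
# expression) to test the bookkeeping operations in isolation.
comm_from_prob <- function(prob, pathways, pvals = NULL) {
  structure(list(prob = prob, pathway_of_pair = pathways,
                 clusters = seq_len(dim(prob)[1]), Kh = 0.5,
                 nperm = if (is.null(pvals)) 0L else 100L, pvals = pvals),
            class = "communication")
}

test_that("Hill closed forms: midpoint, zero ligand, worked value", {
  hill <- function(L, R, Kh) L * R / (Kh + L * R)
  expect_equal(hill(1, 0.5, 0.5), 0.5)          # L*R = Kh -> 0.5
  expect_equal(hill(0, 3, 0.5), 0)              # no ligand -> 0
  expect_equal(hill(1, 1, 0.5), 1 / 1.5)        # worked value ~ 0.6667

  # through the full operation: two clusters with engineered expression
  m <- rbind(LIG = c(60, 60, 0, 0), REC = c(0, 0, 60, 60),
             HK1 = c(40, 40, 40, 40), HK2 = c(50, 50, 50, 50))
  colnames(m) <- paste0("c", 1:4)
  db <- lr_database(data.frame(pathway = "P", ligand = "LIG",
                               receptor = "REC"))
  comm <- communication_probability(m, c(1, 1, 2, 2), db, Kh = 0.5)
  L <- mean(log1p(m["LIG", 1:2] * median(colSums(m)) / colSums(m)[1:2]))
  R <- mean(log1p(m["REC", 3:4] * median(colSums(m)) / colSums(m)[3:4]))
  expect_equal(comm$prob[1, 2, 1], L * R / (0.5 + L * R))
  expect_equal(comm$prob[2, 1, 1], 0)           # receiver has no ligand
  expect_true(all(comm$prob >= 0 & comm$prob <= 1))
})

test_that("a zero receptor subunit nullifies the complex (geometric mean)", {
  m <- rbind(LIG = c(30, 30, 30, 30), R1 = c(20, 20, 20, 20),
             R2 = c(0, 0, 20, 20), HK = c(30, 30, 30, 30))
  colnames(m) <- paste0("c", 1:4)
  db <- lr_database(data.frame(pathway = "P", ligand = "LIG",
                               receptor = "R1,R2"))
  comm <- communication_probability(m, c(1, 1, 2, 2), db, Kh = 0.5)
  expect_equal(comm$prob[1, 1, 1], 0)           # cluster 1 lacks R2 entirely
  expect_gt(comm$prob[1, 2, 1], 0)
})

test_that("probability is monotone nondecreasing in ligand and receptor", {
  hill <- function(L, R, Kh = 0.5) L * R / (Kh + L * R)
  L <- seq(0, 5, by = 0.5)
  expect_true(all(diff(hill(L, 2)) >= 0))
  expect_true(all(diff(hill(3, L)) >= 0))
  expect_true(all(hill(L, 100) <= 1))
})

test_that("interaction strengths sum rows and columns of significant pairs", {
  prob <- array(0, dim = c(2, 2, 1))
  prob[1, 2, 1] <- 0.3; prob[2, 1, 1] <- 0.1; prob[2, 2, 1] <- 0.2
  comm <- comm_from_prob(prob, c(pair1 = "P"))
  st <- interaction_strengths(comm)             # no pvals: nothing filtered
  expect_equal(st$strengths$outgoing, c(0.3, 0.3))
  expect_equal(st$strengths$incoming, c(0.1, 0.5))

  single <- array(0, dim = c(3, 3, 1))
  single[1, 2, 1] <- 0.4
  st2 <- interaction_strengths(comm_from_prob(single, c(p = "P")))
  expect_equal(st2$strengths$outgoing, c(0.4, 0, 0))
  expect_equal(st2$strengths$incoming, c(0, 0.4, 0))
  expect_equal(st2$roles$sender, c(0.4, 0, 0))
  expect_equal(st2$roles$receiver, c(0, 0.4, 0))
  expect_equal(st2$roles$influencer, c(0.4, 0.4, 0))

  # symmetric tensor -> outgoing == incoming
  sym <- array(0, dim = c(3, 3, 2))
  sym[, , 1] <- matrix(c(0, .2, .1, .2, 0, .3, .1, .3, 0), 3, 3)
  sym[, , 2] <- 0.5 * sym[, , 1]
  st3 <- interaction_strengths(comm_from_prob(sym, c(a = "A", b = "B")))
  expect_equal(st3$strengths$outgoing, st3$strengths$incoming)
})

test_that("mediator role reflects flow betweenness through a relay cluster", {
  # chain 1 -> 2 -> 3: only cluster 2 relays flow
  prob <- array(0, dim = c(3, 3, 1))
  prob[1, 2, 1] <- 0.5; prob[2, 3, 1] <- 0.5
  st <- interaction_strengths(comm_from_prob(prob, c(p = "P")))
  med <- st$roles$mediator
  expect_gt(med[2], med[1])
  expect_gt(med[2], med[3])
})

test_that("significance filtering zeroes non-significant entries", {
  prob <- array(0.5, dim = c(2, 2, 1))
  pv <- array(c(0.01, 0.5, 0.2, 0.04), dim = c(2, 2, 1))
  comm <- comm_from_prob(prob, c(p = "P"), pvals = pv)
  st <- interaction_strengths(comm, alpha = 0.05)
  expect_equal(st$strengths$outgoing, c(0.5, 0.5))
  expect_equal(st$strengths$incoming, c(0.5, 0.5))
  expect_equal(sum(information_flow(comm, alpha = 0.05)), 1.0)
})

test_that("permutation p-values are seed-deterministic and detect design", {
  design <- default_lr_design()
  cfg <- sim_config(cells_per_state = rep(60L, 4), lr_design = design,
                    seed = 17)
  ds <- generate_emt_dataset(cfg)
  labels <- ds$true_state
  comm1 <- suppressWarnings(
    permutation_significance(ds$counts, labels, ds$lr_db, nperm = 50,
                             seed = 99))
  comm2 <- suppressWarnings(
    permutation_significance(ds$counts, labels, ds$lr_db, nperm = 50,
                             seed = 99))
  expect_identical(comm1$pvals, comm2$pvals)

  # the designed NotchToy I2 -> M edge must be significant
  i2 <- match("I2", cfg$state_labels); m <- match("M", cfg$state_labels)
  notch <- grep("NotchToy", dimnames(comm1$prob)[[3]])
  expect_lt(comm1$pvals[i2, m, notch], 0.05)
  expect_error(permutation_significance(ds$counts, labels, ds$lr_db,
                                        nperm = 0), "nperm")
})

test_that("information flow and condition comparison bookkeeping", {
  zero <- array(0, dim = c(2, 2, 2))
  comm0 <- comm_from_prob(zero, c(x = "X", y = "Y"))
  expect_equal(unname(information_flow(comm0)), c(0, 0))

  # two pathways with total probs 0.6 and 0.3 -> relative flows 2/3, 1/3
  pr <- array(0, dim = c(2, 2, 2))
  pr[1, 2, 1] <- 0.6; pr[1, 2, 2] <- 0.3
  commA <- comm_from_prob(pr, c(x = "X", y = "Y"))
  tab1 <- compare_conditions(list(A = commA))
  expect_equal(tab1$rel_flow[tab1$pathway == "X"], 2 / 3)
  expect_equal(tab1$rel_flow[tab1$pathway == "Y"], 1 / 3)

  # pathway significant only in condition A -> flagged exclusive
  prB <- array(0, dim = c(2, 2, 2))
  prB[1, 2, 2] <- 0.2
  commB <- comm_from_prob(prB, c(x = "X", y = "Y"))
  tab <- compare_conditions(list(A = commA, B = commB))
  xa <- tab[tab$pathway == "X" & tab$condition == "A", ]
  expect_true(xa$exclusive)
  expect_false(any(tab$exclusive[tab$pathway == "Y"]))

  comm_other <- comm_from_prob(pr, c(x = "Z1", y = "Z2"))
  expect_error(compare_conditions(list(A = commA, B = comm_other)),
               "disjoint")
  expect_error(compare_conditions(list(commA, commB)), "named")
})
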