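make_toy <- function() {
  lmadj <- matrix(c(1, 0, 0, 1, 1, 0), 2, 3,
                  dimnames = list(c("l1", "l2"), c("m1", "m2", "m3")))
  lm <- interaction_network(lmadj)
  sl <- matrix(c(1, .4, .4, 1), 2, dimnames = list(c("l1", "l2"), c("l1", "l2")))
  sm <- diag(3); dimnames(sm) <- list(c("m1", "m2", "m3"), c("m1", "m2", "m3"))
  list(lm = lm, sl = sl, sm = sm)
}

test_that("bilayer assembly places blocks per the block-matrix layout", {
  toy <- make_toy()
  net <- build_bilayer(toy$lm, toy$sl, toy$sm)
  expect_equal(dim(net$A), c(5, 5))
  expect_equal(net$A[1, 3], toy$lm$lm[1, 1])       # LM block starts at column m+1
  expect_identical(net$A[1:2, 1:2], toy$sl)
  expect_identical(unname(net$A[3:5, 3:5]), unname(toy$sm))
  expect_identical(unname(net$A[1:2, 3:5]), unname(toy$lm$lm))
  expect_identical(net$A, t(net$A))
  # identity similarities and no interactions give the identity bilayer
  lm0 <- interaction_network(matrix(0, 2, 3,
           dimnames = list(c("l1", "l2"), c("m1", "m2", "m3"))))
  net0 <- build_bilayer(lm0, diag(2) |> `dimnames<-`(list(c("l1","l2"), c("l1","l2"))),
                        toy$sm)
  expect_equal(unname(net0$A), diag(5))
})

test_that("bilayer construction rejects mismatched ids and bad adjacency", {
  toy <- make_toy()
  slbad <- toy$sl
  rownames(slbad) <- colnames(slbad) <- c("l1", "lX")
  expect_error(build_bilayer(toy$lm, slbad, toy$sm), "lX")
  expect_error(interaction_network(matrix(2, 1, 1)), "0 or 1")
})

test_that("ablation zeroes exactly the omitted similarity blocks", {
  toy <- make_toy()
  net <- build_bilayer(toy$lm, toy$sl, toy$sm)
  a_lm <- ablate_bilayer(net, "lm")
  expect_true(all(a_lm$A[1:2, 1:2] == 0) && all(a_lm$A[3:5, 3:5] == 0))
  expect_identical(a_lm$A[1:2, 3:5], net$A[1:2, 3:5])
  a_sl <- ablate_bilayer(net, "lm+sl")
  expect_identical(a_sl$A[1:2, 1:2], net$A[1:2, 1:2])
  expect_true(all(a_sl$A[3:5, 3:5] == 0))
  expect_identical(ablate_bilayer(net, "bilayer")$A, net$A)
})

test_that("perturbation splits partition the edges exactly", {
  sim <- simulate_lmi(m = 15, n = 10, seed = 5)
  net <- build_bilayer(sim$lm, sim$sl, sim$sm)
  pool_n <- sum(net$A[upper.tri(net$A)] != 0)
  sp <- sample_perturbation_split(net, fraction = 0.1, seed = 3)
  expect_equal(nrow(sp$E_p), round(0.1 * pool_n))
  expect_identical(sp$A_r + sp$A_p, net$A)          # exact, not approximate
  expect_equal(sp$A_p, t(sp$A_p))
  expect_true(all(sp$A_r[sp$A_p != 0] == 0))        # disjoint supports
  expect_true(all(diag(sp$A_p) == 0))               # diagonal never sampled
  sp2 <- sample_perturbation_split(net, fraction = 0.1, seed = 3)
  expect_identical(sp$E_p, sp2$E_p)                 # seeded determinism
  expect_error(sample_perturbation_split(net, fraction = 1.2), "fraction")
})

test_that("half splits of a four-edge graph always reassemble the network", {
  adj <- matrix(0, 3, 3, dimnames = list(paste0("l", 1:3), paste0("m", 1:3)))
  adj[1, 1] <- adj[1, 2] <- adj[2, 3] <- adj[3, 1] <- 1
  net <- lm_only_bilayer(adj)
  all_pairs <- apply(edge_pairs <- which(upper.tri(net$A) & net$A != 0,
                                         arr.ind = TRUE), 1, paste, collapse = "-")
  seen <- character(0)
  for (s in 1:40) {
    sp <- sample_perturbation_split(net, fraction = 0.5, seed = s)
    expect_equal(nrow(sp$E_p), 2)
    expect_identical(sp$A_r + sp$A_p, net$A)
    seen <- union(seen, paste(apply(sp$E_p, 1, paste, collapse = "-"),
                              collapse = "|"))
    expect_true(all(apply(sp$E_p, 1, paste, collapse = "-") %in% all_pairs))
  }
  expect_gt(length(seen), 1)   # draws vary across seeds
})

test_that("alignment pads missing ids with zero rows and keeps links", {
  adj <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("l1", "l2"), c("m1", "m2")))
  lm <- interaction_network(adj)
  big <- align_interactions(lm, c("l0", "l1", "l2"), c("m1", "m2", "m3"))
  expect_equal(dim(big$lm), c(3, 3))
  expect_equal(sum(big$lm), sum(adj))
  expect_identical(big$lm[c("l1", "l2"), c("m1", "m2")], adj)
  expect_true(all(big$lm["l0", ] == 0) && all(big$lm[, "m3"] == 0))
  expect_error(align_interactions(lm, c("l1"), c("m1", "m2")), "l2")
})

test_that("interaction pool restricts removal to interaction links", {
  sim <- simulate_lmi(m = 15, n = 10, seed = 6)
  net <- build_bilayer(sim$lm, sim$sl, sim$sm)
  sp <- sample_perturbation_split(net, fraction = 0.2, seed = 1,
                                  pool = "interaction")
  expect_true(all(sp$E_p[, 1] <= net$m & sp$E_p[, 2] > net$m))
  expect_equal(nrow(sp$E_p), round(0.2 * sum(sim$lm$lm)))
})
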