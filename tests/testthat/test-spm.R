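test_that("eigen system reconstructs and groups degenerate eigenvalues", {
  es <- eigen_system(diag(c(1, 2, 3)))
  expect_equal(es$values, c(1, 2, 3))
  expect_equal(abs(es$vectors), diag(3), tolerance = 1e-12)
  expect_length(es$groups, 3)
  es2 <- eigen_system(diag(2))
  expect_length(es2$groups, 1)
  expect_length(es2$groups[[1]], 2)
  set.seed(41)
  a <- rand_sym(6)
  es3 <- eigen_system(a)
  recon <- es3$vectors %*% (es3$values * t(es3$vectors))
  expect_lt(max(abs(recon - a)), 1e-8 * max(1, max(abs(es3$values))))
  expect_error(eigen_system(matrix(1:4, 2)), "symmetric")
})

test_that("zero and commuting perturbations are reproduced exactly", {
  set.seed(42)
  a <- rand_sym(7)
  expect_equal(perturb_once(raw_split(a, matrix(0, 7, 7))), a,
               tolerance = 1e-9)
  expect_equal(perturb_once(raw_split(a, 0.5 * a)), 1.5 * a,
               tolerance = 1e-9)
  # fully degenerate base: the subspace rotation must diagonalise A_p itself
  p <- rand_sym(7)
  expect_equal(perturb_once(raw_split(diag(7), p)), diag(7) + p,
               tolerance = 1e-9)
})

test_that("perturbation conserves the trace for any split", {
  set.seed(43)
  for (rep in 1:10) {
    a_r <- rand_sym(8)
    a_p <- rand_sym(8)
    expect_equal(sum(diag(perturb_once(raw_split(a_r, a_p)))),
                 sum(diag(a_r)) + sum(diag(a_p)), tolerance = 1e-9)
  }
  # degenerate spectrum
  a_p <- rand_sym(6)
  expect_equal(sum(diag(perturb_once(raw_split(diag(6), a_p)))),
               6 + sum(diag(a_p)), tolerance = 1e-9)
})

test_that("eigenvalue corrections match a finite-difference oracle", {
  set.seed(44)
  for (rep in 1:5) {
    a_r <- rand_sym(8)
    a_p <- rand_sym(8)
    es <- eigen_system(a_r)
    dl <- vapply(seq_len(8), function(k)
      drop(crossprod(es$vectors[, k], a_p %*% es$vectors[, k])), numeric(1))
    eps <- 1e-6
    fd <- (eigen(a_r + eps * a_p, symmetric = TRUE, only.values = TRUE)$values -
           eigen(a_r - eps * a_p, symmetric = TRUE, only.values = TRUE)$values) /
          (2 * eps)
    expect_equal(sort(dl), sort(fd), tolerance = 1e-6)
  }
})

test_that("degenerate grouping reduces to the simple formula for singletons", {
  set.seed(45)
  a_r <- rand_sym(6)
  a_p <- rand_sym(6)
  # forcing every eigenvalue into its own group must equal the default path
  # (spectra of rand_sym are simple, so groups are singletons already)
  expect_equal(perturb_once(raw_split(a_r, a_p), tol_factor = 1e-300),
               perturb_once(raw_split(a_r, a_p)), tolerance = 1e-12)
  # exact two-fold degeneracy handled through the subspace rotation
  q <- qr.Q(qr(rand_sym(4)))
  a_r2 <- q %*% (c(2, 2, 5, 7) * t(q))
  a_r2 <- (a_r2 + t(a_r2)) / 2
  a_p2 <- rand_sym(4, scale = 1e-4)
  at <- perturb_once(raw_split(a_r2, a_p2))
  exact <- eigen(a_r2 + a_p2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(eigen(at, symmetric = TRUE, only.values = TRUE)$values),
               sort(exact), tolerance = 1e-6)
})

test_that("perturbed matrix is equivariant under node relabelling", {
  set.seed(46)
  a_r <- rand_sym(7)
  a_p <- rand_sym(7)
  at <- perturb_once(raw_split(a_r, a_p))
  perm <- sample(7)
  at_perm <- perturb_once(raw_split(a_r[perm, perm], a_p[perm, perm]))
  expect_equal(at_perm, at[perm, perm], tolerance = 1e-8)
})

test_that("t-averaged prediction is symmetric, seeded and reduces to one draw", {
  sim <- simulate_lmi(m = 20, n = 12, seed = 9)
  fit1 <- spmc(sim$lm, sim$sl, sim$sm, t = 1, fraction = 0.1, seed = 4)
  net <- build_bilayer(sim$lm, sim$sl, sim$sm)
  sp <- sample_perturbation_split(net, 0.1, seed = fit1$sub_seeds[[1]],
                                  pool = "all")
  expect_equal(fit1$A_tilde, perturb_once(sp), tolerance = 1e-12)
  fit <- spmc(sim$lm, sim$sl, sim$sm, t = 5, fraction = 0.1, seed = 4)
  expect_equal(fit$A_tilde, t(fit$A_tilde), tolerance = 1e-9)
  refit <- spmc(sim$lm, sim$sl, sim$sm, t = 5, fraction = 0.1, seed = 4)
  expect_identical(fit$A_tilde, refit$A_tilde)
  expect_equal(sum(diag(fit$A_tilde)), sum(diag(net$A)), tolerance = 1e-9)
})

test_that("held-out true links outscore never-linked pairs on planted data", {
  sim <- simulate_lmi(seed = 8)
  set.seed(88)
  pos <- which(sim$lm$lm == 1)
  held <- sample(pos, round(0.2 * length(pos)))
  train <- sim$lm$lm
  train[held] <- 0
  fit <- spmc(interaction_network(train, sim$lm$lnc_ids, sim$lm$mi_ids),
              sim$sl, sim$sm, t = 8, seed = 2)
  never <- which(sim$lm$lm == 0)
  expect_gt(mean(fit$scores[held]), mean(fit$scores[never]))
})

test_that("candidate ranking is ordered, masked and id-addressed", {
  sim <- simulate_lmi(m = 20, n = 12, seed = 10)
  fit <- spmc(sim$lm, sim$sl, sim$sm, t = 4, seed = 3)
  rc <- rank_candidates(fit, "lnc001", "mirnas_for_lncrna", top_k = 5)
  expect_equal(nrow(rc), 5)
  expect_true(all(diff(rc$score) <= 0))
  expect_false(any(rc$known))
  rc_all <- rank_candidates(fit, "lnc001", "mirnas_for_lncrna", top_k = 100,
                            exclude_known = FALSE)
  expect_equal(nrow(rc_all), 12)    # capped at the candidate count
  expect_error(rank_candidates(fit, "nope", "mirnas_for_lncrna"), "nope")
  pr <- predict(fit, top_k = 10)
  expect_equal(nrow(pr), 10)
  expect_true(all(diff(pr$score) <= 0))
  expect_false(any(pr$known))
})

test_that("dropping a query's links removes exactly that row or column", {
  sim <- simulate_lmi(m = 10, n = 8, seed = 12)
  lnc <- sim$lm$lnc_ids[1]
  dropped <- drop_interactions(sim$lm, lnc)
  expect_true(all(dropped$lm[lnc, ] == 0))
  expect_identical(dropped$lm[-1, ], sim$lm$lm[-1, ])
  expect_error(drop_interactions(sim$lm, "ghost"), "ghost")
})
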