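# AMOVA / R_ST / MDS against loop-based and hand-computed oracles.

test_that("repeat distance is the summed squared difference", {
  expect_equal(repeat_distance(c(14, 30, 12), c(14, 30, 12)), 0)
  expect_equal(repeat_distance(c(14, 30, 12), c(14, 32, 12)), 4)
  set.seed(5)
  for (rep in 1:10) {
    a <- sample(8:20, 23, replace = TRUE)
    b <- sample(8:20, 23, replace = TRUE)
    brute <- 0
    for (l in seq_along(a)) brute <- brute + (a[l] - b[l])^2
    expect_equal(repeat_distance(a, b), brute)
    expect_equal(repeat_distance(a, b), repeat_distance(b, a))
  }
  expect_error(repeat_distance(1:3, 1:4), "length")
})

test_that("repeat matrix requires adjustment and filtering", {
  t <- make_table(DYS19 = c("15", "16"))
  expect_error(repeat_matrix(t), "adjust_dys389")
  ta <- adjust_dys389(t)
  M <- repeat_matrix(ta)
  expect_equal(dim(M), c(2L, 23L))
  expect_equal(unname(M[, "DYS389II"]), c(16, 16)) # 29 - 13
  tn <- make_table(DYS448 = c("19", ""))
  tn <- adjust_dys389(tn)
  expect_error(repeat_matrix(tn), "filter_for_network")
})

test_that("two-level AMOVA matches the hand-computed P = 2, n = 3 + 3 oracle", {
  A <- matrix(c(10, 11, 10), ncol = 1)
  B <- matrix(c(13, 14, 13), ncol = 1)
  r <- amova_two_level(list(A, B))
  # worked by hand from the defining formulas:
  # pairwise squared diffs: within A 1+0+1, within B 1+0+1, across 85
  expect_equal(r$ssd_total, 89 / 6, tolerance = 1e-12)
  expect_equal(r$ssd_within, 4 / 3, tolerance = 1e-12)
  expect_equal(r$ssd_among, 13.5, tolerance = 1e-12)
  expect_equal(r$df_among, 1L)
  expect_equal(r$df_within, 4L)
  expect_equal(r$sigma2_w, 1 / 3, tolerance = 1e-12)
  expect_equal(r$n_prime, 3, tolerance = 1e-12)
  expect_equal(r$sigma2_a, (13.5 - 1 / 3) / 3, tolerance = 1e-12)
  expect_equal(r$phi_st, 0.929412, tolerance = 1e-6)
})

test_that("AMOVA agrees with the loop oracle and SSD is additive", {
  set.seed(13)
  for (rep in 1:8) {
    P <- sample(2:4, 1)
    groups <- lapply(seq_len(P), function(p)
      matrix(sample(10:16, sample(2:6, 1) * 5, replace = TRUE), ncol = 5))
    r <- amova_two_level(groups)
    o <- oracle_amova(groups)
    expect_equal(r$ssd_total, o$ssd_total, tolerance = 1e-9)
    expect_equal(r$ssd_within, o$ssd_within, tolerance = 1e-9)
    expect_equal(r$sigma2_a, o$sigma2_a, tolerance = 1e-9)
    expect_equal(r$phi_st, o$phi_st, tolerance = 1e-9)
    expect_equal(r$ssd_total, r$ssd_among + r$ssd_within,
                 tolerance = 1e-9 * max(1, r$ssd_total))
    expect_lte(r$phi_st, 1)
  }
})

test_that("AMOVA degenerate and extreme cases", {
  # identical populations: no among-group signal, clamped to 0
  A <- matrix(rep(c(12, 14), each = 10), ncol = 2)
  r0 <- amova_two_level(list(A, A))
  expect_equal(r0$ssd_among, 0, tolerance = 1e-9)
  expect_lte(r0$phi_st, 0)
  expect_equal(r0$phi_st_clamped, 0)
  # fixed populations one repeat step apart: all variance among
  F1 <- matrix(rep(14, 10), ncol = 1)
  F2 <- matrix(rep(15, 10), ncol = 1)
  r1 <- amova_two_level(list(F1, F2))
  expect_equal(r1$ssd_within, 0)
  expect_equal(r1$phi_st, 1)
  # scaling all repeat differences leaves Phi unchanged
  set.seed(21)
  g <- lapply(1:2, function(p) matrix(sample(10:14, 12, replace = TRUE), ncol = 2))
  g3 <- lapply(g, function(m) m * 3)
  expect_equal(amova_two_level(g)$phi_st, amova_two_level(g3)$phi_st,
               tolerance = 1e-9)
  # single group and all-singleton groups are errors, not crashes
  expect_error(amova_two_level(list(F1)), "two groups")
  expect_error(amova_two_level(list(matrix(14), matrix(15), matrix(16))),
               "n = 1")
})

test_that("permutation test is seeded, reproducible and hits the minimal p", {
  F1 <- matrix(rep(14, 10), ncol = 1)
  F2 <- matrix(rep(15, 10), ncol = 1)
  p1 <- phi_permutation_test(list(F1, F2), n_perm = 999, seed = 1)
  p2 <- phi_permutation_test(list(F1, F2), n_perm = 999, seed = 1)
  expect_equal(p1$p_value, p2$p_value)
  expect_equal(p1$p_value, 0.001) # no permutation reaches the observed split
  # identical groups: observed Phi is unexceptional
  A <- matrix(sample(10:15, 20, replace = TRUE), ncol = 2)
  pn <- phi_permutation_test(list(A, A), n_perm = 99, seed = 2)
  expect_gt(pn$p_value, 0.05)
})

test_that("rst_matrix is symmetric, zero-diagonal and zero for identical groups", {
  t <- make_table(DYS19 = rep(c("15", "16"), 6),
                  tribe = rep(c("A", "B"), each = 6))
  # tribes A and B have identical haplotype composition
  t$calls[, "DYS19"] <- rep(c("15", "16"), 6)
  r <- rst_matrix(t, group_by = "tribe")
  expect_equal(r$d, t(r$d))
  expect_equal(unname(diag(r$d)), c(0, 0))
  expect_equal(max(r$d), 0)
  sim <- simulate_population(simulation_config(n = 90, seed = 5))
  r2 <- rst_matrix(sim$table, group_by = "tribe")
  expect_equal(r2$d, t(r2$d))
  expect_true(all(diag(r2$d) == 0))
  expect_true(all(r2$d <= 1))
})

test_that("R_ST grows with founder divergence time", {
  # populations expanded from founders separated by increasing tau
  set.seed(17)
  taus <- c(0, 4, 16, 64)
  mean_rst <- vapply(taus, function(tau) {
    phis <- vapply(1:12, function(rep) {
      anc <- simulate_tribe(n = 1, generations = tau,
                            seed = 1000L + 17L * rep + tau)
      fB <- founder_from_vector(anc$truth_vectors[1, ])
      a <- simulate_tribe(default_founder(), n = 12, generations = 6,
                          seed = 2000L + rep)
      b <- simulate_tribe(fB, n = 12, generations = 6, seed = 3000L + rep)
      amova_two_level(list(a$truth_vectors, b$truth_vectors))$phi_st_clamped
    }, 0)
    mean(phis)
  }, 0)
  expect_equal(order(mean_rst), seq_along(taus))
})

test_that("classical MDS embeds exactly when possible and reports stress", {
  # two points at distance 0.5
  d2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  m2 <- classical_mds(d2, k = 1)
  expect_equal(stats::dist(m2$coordinates)[1], 0.5, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m2$stress, 0, tolerance = 1e-12)
  # a 3-4-5 right triangle embeds exactly in the plane
  d3 <- matrix(0, 3, 3)
  d3[1, 2] <- d3[2, 1] <- 3; d3[1, 3] <- d3[3, 1] <- 4
  d3[2, 3] <- d3[3, 2] <- 5
  m3 <- classical_mds(d3, k = 2)
  expect_lt(m3$stress, 1e-10)
  # stress is monotone in the embedding dimension
  set.seed(9)
  X <- matrix(runif(24), 6)
  d6 <- as.matrix(stats::dist(X))^0.7 # deliberately non-Euclidean
  expect_lte(classical_mds(d6, k = 5)$stress,
             classical_mds(d6, k = 2)$stress + 1e-12)
  # rigid motion of the configuration leaves stress unchanged
  theta <- 0.83
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  m <- classical_mds(d6, k = 2)
  rot <- m$coordinates %*% R
  drot <- as.matrix(stats::dist(rot))
  ut <- upper.tri(d6)
  expect_equal(sqrt(sum((d6 - drot)[ut]^2) / sum(d6[ut]^2)), m$stress,
               tolerance = 1e-9)
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2), k = 1), "symmetric")
})
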