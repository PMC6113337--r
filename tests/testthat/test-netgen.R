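test_that("project_omega symmetrizes then clips", {
  X <- matrix(c(0.2, 0.2, 0.6, 0.6), 2)
  P <- project_omega(X)
  expect_equal(P[1, 2], 0.4)
  expect_equal(P[2, 1], 0.4)
  Y <- matrix(c(1.3, 0.5, 0.5, -0.2), 2)
  expect_equal(project_omega(Y), matrix(c(1, 0.5, 0.5, 0), 2))
  Z <- matrix(c(0.1, 0.4, 0.4, 0.9), 2)
  expect_equal(project_omega(Z), Z)
  expect_error(project_omega(matrix(c(1, Inf, Inf, 1), 2)), "finite")
})

test_that("noise generators hit their degenerate and stochastic contracts", {
  expect_equal(gen_sparse_noise(10, 0, seed = 1), matrix(0, 10, 10))
  expect_equal(gen_dense_noise(10, 0, seed = 1), matrix(0, 10, 10))
  S1 <- gen_sparse_noise(20, 1, seed = 2)
  expect_true(all(S1[upper.tri(S1, diag = TRUE)] != 0))

  # p_s = 0.1, N = 900: upper-triangle support within 3 binomial sd of 0.1
  S <- gen_sparse_noise(900, 0.1, seed = 3)
  m <- 900 * 901 / 2
  frac <- sum(S[upper.tri(S, diag = TRUE)] != 0) / m
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / m))
  expect_identical(S, t(S))
  expect_true(all(abs(S) < 1))

  E <- gen_dense_noise(50, 0.1, seed = 4)
  expect_true(all(abs(E) < 0.1))
  expect_identical(E, t(E))
  # determinism
  expect_identical(gen_sparse_noise(30, 0.2, seed = 9),
                   gen_sparse_noise(30, 0.2, seed = 9))
})

test_that("factor low-rank component has the planted block structure", {
  memb <- block_labels(c(10, 10, 10))
  spec <- factor_spec(r_in = 0.6, r_out = 0)
  L <- gen_factor_L(memb, spec, seed = 5)
  # r_out = 0: exactly block-diagonal with rank K
  expect_equal(qr(L)$rank, 3L)
  expect_true(all(L[1:10, 11:30] == 0))
  expect_true(all(L[1:10, 1:10] >= 0.6^2))

  # single community
  L1 <- gen_factor_L(rep(0L, 8), spec, seed = 5)
  expect_equal(qr(L1)$rank, 1L)

  # outliers draw all loadings from the non-member law; absent rows are zero
  memb2 <- c(rep(0L, 5), -1L, NA)
  L2 <- gen_factor_L(memb2, factor_spec(), seed = 6)
  expect_true(all(L2[7, ] == 0))
  expect_true(all(L2[6, -7] < 0.4^2 * 2))
  expect_error(gen_factor_L(memb, factor_spec(r_in = 0.3, r_out = 0.4)),
               "r_out < r_in")
})

test_that("SBM snapshots are binary with the designed within-density", {
  memb <- block_labels(c(60, 60))
  A <- gen_sbm_A(memb, sbm_spec(p_c = 1, p_flip = 0), seed = 1)
  expect_true(all(A[1:60, 1:60] == 1))
  expect_true(all(A[1:60, 61:120] == 0))

  A2 <- gen_sbm_A(memb, sbm_spec(p_c = 0.3), seed = 2)
  expect_true(all(A2 %in% c(0, 1)))
  # within-block density: p_c + flips, bounded by clipping; off-block: 0.05
  within <- mean(A2[1:60, 1:60])
  expect_lt(abs(within - (0.3 + 0.05 * 0.7 - 0.05 * 0.3)), 0.05)
  off <- mean(A2[1:60, 61:120])
  expect_lt(abs(off - 0.05), 0.02)
})

test_that("WSBM segment averages approach the 0.7 / 0.3 heuristic", {
  memb <- block_labels(c(50, 50))
  spec <- wsbm_spec(ub = 0.6, p_s = 0, r = 0)
  As <- lapply(1:40, function(t)
    gen_wsbm_A(memb, spec, seed = t,
               L = netphase:::segment_L(memb, spec, seed = t)))
  A_bar <- Reduce(`+`, As) / length(As)
  ut <- upper.tri(A_bar)
  expect_lt(abs(mean(A_bar[1:50, 1:50][upper.tri(A_bar[1:50, 1:50])]) - 0.7),
            0.03)
  expect_lt(abs(mean(A_bar[1:50, 51:100]) - 0.3), 0.03)
  # ub = 0.9: in/out ranges nearly overlap (weak signal by design)
  sp9 <- wsbm_spec(ub = 0.9)
  expect_lt(mean(sp9$in_range) - mean(sp9$out_range), 0.2)
  expect_error(wsbm_spec(ub = 1), "dominate")
})

test_that("build_scenario presets carry coherent planted truth", {
  sc <- build_scenario("three-model-small", seed = 2)
  expect_length(sc$network$snapshots, 30L)
  expect_equal(sc$truth$epochs, list(c(10L, 10L), c(20L, 20L)))
  m <- sc$truth$membership
  expect_equal(length(unique(m[1, ])), 12L)   # 11 communities + outliers
  expect_equal(length(setdiff(unique(m[15, ]), -1L)), 9L)
  expect_equal(length(setdiff(unique(m[25, ]), -1L)), 7L)

  # identical seeds give byte-identical output
  sc2 <- build_scenario("three-model-small", seed = 2)
  expect_identical(sc$network$snapshots[[7]]$matrix,
                   sc2$network$snapshots[[7]]$matrix)
  expect_identical(sc$truth$membership, sc2$truth$membership)
  sc3 <- build_scenario("three-model-small", seed = 3)
  expect_false(identical(sc$network$snapshots[[7]]$matrix,
                         sc3$network$snapshots[[7]]$matrix))
  expect_error(build_scenario("nope"), "available")
})

test_that("illustrative preset tracks joins, leaves and splits", {
  sc <- build_scenario("illustrative-small", seed = 1)
  sizes <- vapply(sc$network$snapshots, function(s) length(s$node_ids),
                  integer(1))
  expect_equal(sizes[c(1, 9)], c(300L, 300L))
  expect_equal(sizes[c(10, 18)], c(333L, 333L))   # join at the first epoch
  expect_equal(sizes[c(21, 39)], c(300L, 300L))   # joiners left
  expect_equal(sizes[c(42, 60)], c(333L, 333L))   # reverted
  m <- sc$truth$membership
  counts <- function(t) length(setdiff(unique(m[t, !is.na(m[t, ])]), -1L))
  expect_equal(vapply(c(5, 15, 30, 50), counts, integer(1)),
               c(11L, 11L, 7L, 12L))
})

test_that("wsbm-split preset splits the large community at t = 21", {
  sc <- build_scenario("wsbm-split", seed = 4)
  m <- sc$truth$membership
  expect_equal(length(sc$network$snapshots), 40L)
  expect_equal(sum(m[1, ] == 0L), 200L)
  expect_equal(sum(m[21, ] == 0L), 125L)
  expect_equal(sum(m[21, ] == 4L), 75L)
  expect_true(all(sc$network$snapshots[[33]]$matrix >= 0) &&
                all(sc$network$snapshots[[33]]$matrix <= 1))
})
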