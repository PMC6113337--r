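test_that("gen_support meets exact in/out degree constraints", {
  # one community of 16, in-degree 14, no cross edges
  C <- gen_support(16L, seed = 1, out_degree = 0L)
  expect_true(all(rowSums(C) == 14))
  expect_identical(C + 0, t(C + 0))
  expect_true(all(diag(C) == 0))

  # two communities, one cross edge per node
  C2 <- gen_support(c(16L, 16L), seed = 2)
  cross <- C2[1:16, 17:32]
  expect_true(all(rowSums(cross) == 1))
  expect_true(all(colSums(cross) == 1))
  expect_true(all(rowSums(C2[1:16, 1:16]) == 14))
  # merged community sizes used by the four-period preset (period 2)
  sizes <- c(64L, 48L, 48L, 32L, 32L, 16L, 16L)
  C3 <- gen_support(sizes, seed = 3)
  expect_true(all(rowSums(C3[1:64, 1:64]) == 56))         # 14 * 64 / 16
  expect_true(all(rowSums(C3[65:112, 65:112]) == 42))     # 14 * 48 / 16
  memb <- rep(seq_along(sizes), sizes)
  cross_deg <- vapply(seq_len(256), function(i)
    sum(C3[i, memb != memb[i]]), numeric(1))
  expect_true(all(cross_deg == 1))
  expect_error(gen_support(c(15L, 16L), seed = 1), "not an integer")
})

test_that("hierarchical support has per-level degrees (15, 3, 1)", {
  C <- gen_support_hierarchical(seed = 7)
  m1 <- attr(C, "membership"); m2 <- attr(C, "membership2")
  expect_equal(dim(C), c(256L, 256L))
  for (i in c(1L, 40L, 200L)) {
    same1 <- m1 == m1[i]
    same2 <- m2 == m2[i] & !same1
    expect_equal(sum(C[i, same1]) , 15)
    expect_equal(sum(C[i, same2]), 3)
    expect_equal(sum(C[i, !same1 & !same2]), 1)
  }
  expect_identical(C + 0, t(C + 0))
})

test_that("decoupled oscillators drift linearly (kappa = 0 closed form)", {
  C <- gen_support(c(8L, 8L), seed = 1)  # in-degree 7: complete blocks
  omega <- rep(c(-1, 0.5, 2, -0.3, 1, 0, 0.7, -2), 2)
  th0 <- seq(0, 2, length.out = 16)
  traj <- kuramoto_integrate(C, omega, th0, kappa = 0, tau = 0.1,
                             steps = 25L)
  for (s in c(1L, 10L, 25L))
    expect_equal(traj[s, , 1], th0 + omega * s * 0.1, tolerance = 1e-12)
})

test_that("coupled pair synchronizes monotonically; sync is a fixed point", {
  C <- matrix(c(0, 1, 1, 0), 2)
  traj <- kuramoto_integrate(C, c(0, 0), c(0, pi - 0.1), kappa = 0.25,
                             tau = 0.05, steps = 400L)
  gap <- abs(traj[, 2, 1] - traj[, 1, 1])
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[400], 0.05)

  same <- kuramoto_integrate(C, c(0, 0), c(1.3, 1.3), kappa = 0.25,
                             tau = 0.1, steps = 10L)
  expect_true(all(abs(same - 1.3) < 1e-12))
})

test_that("similarity_network averages |cos| with unit diagonal", {
  th <- matrix(0.7, 5, 3)
  expect_equal(similarity_network(th), matrix(1, 5, 5))
  th2 <- c(0, pi / 2)
  A <- similarity_network(th2)
  expect_equal(A[1, 2], 0, tolerance = 1e-12)
  expect_equal(diag(A), c(1, 1))

  # independent uniform phase differences: E|cos| = 2/pi
  th3 <- withr::with_seed(8, matrix(runif(2 * 4000, 0, 2 * pi), 2))
  A3 <- similarity_network(th3)
  expect_lt(abs(A3[1, 2] - 2 / pi), 0.02)
  expect_true(all(A3 >= 0 & A3 <= 1))
})

test_that("kuramoto scenarios are deterministic with planted timelines", {
  ks <- build_kuramoto_scenario("four-period", seed = 3, runs = 2)
  expect_length(ks$network$snapshots, 280L)
  expect_equal(ks$truth$epochs,
               list(c(70L, 71L), c(140L, 141L), c(210L, 211L)))
  counts <- function(t) length(unique(ks$truth$membership[t, ]))
  expect_equal(vapply(c(40, 110, 180, 250), counts, integer(1)),
               c(16L, 7L, 4L, 2L))
  A <- ks$network$snapshots[[40]]$matrix
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(diag(A), rep(1, 256))

  ks2 <- build_kuramoto_scenario("four-period", seed = 3, runs = 2)
  expect_identical(ks$network$snapshots[[123]]$matrix,
                   ks2$network$snapshots[[123]]$matrix)

  kh <- build_kuramoto_scenario("hierarchical", seed = 3, runs = 2)
  expect_length(kh$network$snapshots, 100L)
  expect_length(kh$truth$epochs, 0L)
})

test_that("within-community similarity trends upward early in period 1", {
  ks <- build_kuramoto_scenario("four-period", seed = 5, runs = 6)
  memb <- ks$truth$membership[1, ]
  within_mean <- vapply(c(5, 25, 45, 65), function(t) {
    A <- ks$network$snapshots[[t]]$matrix
    mean(vapply(unique(memb), function(k) {
      idx <- memb == k
      mean(A[idx, idx][upper.tri(A[idx, idx])])
    }, numeric(1)))
  }, numeric(1))
  # trend with tolerance, not strict monotonicity
  expect_gt(within_mean[4], within_mean[1])
  expect_gt(mean(diff(within_mean) > -0.02), 0.5)
})
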