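test_that("default_beta follows 0.15 N^2 / ||A||_1", {
  expect_equal(default_beta(matrix(1, 2, 2)), 0.15)
  # all-c matrix: 0.15/c, independent of N
  expect_equal(default_beta(matrix(0.5, 7, 7)), 0.3)
  expect_equal(default_beta(diag(3)), 0.45)
  expect_error(default_beta(matrix(0, 4, 4)), "all-zero")
})

test_that("soft_threshold shrinks elementwise with sign preservation", {
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(2, 1), 1)
  expect_equal(soft_threshold(-2, 1), -1)
  x <- matrix(rnorm(16), 4)
  expect_equal(soft_threshold(x, 0), x)
  expect_error(soft_threshold(x, -1), "nonnegative")
})

test_that("svt matches analytic cases and the brute-force SVD oracle", {
  expect_equal(svt(diag(3), 0.5), 0.5 * diag(3))
  M <- matrix(rnorm(25), 5)
  expect_equal(svt(M, 0), M, tolerance = 1e-12)
  expect_equal(svt(diag(c(5, 3, 0.1)), 1), diag(c(4, 2, 0)))
  expect_error(svt(matrix(c(1, NA, NA, 1), 2), 1), "finite")

  # oracle: full SVD + elementwise shrinkage, small symmetric instances
  for (seed in 1:5) {
    S <- withr::with_seed(seed, {
      X <- matrix(rnorm(30 * 30), 30); (X + t(X)) / 2
    })
    theta <- withr::with_seed(seed, runif(1, 0.5, 3))
    sv <- svd(S)
    oracle <- sv$u %*% (pmax(sv$d - theta, 0) * t(sv$v))
    expect_equal(svt(S, theta), oracle, tolerance = 1e-10)
    # solver's symmetric path agrees too
    expect_equal(netphase:::svt_sym(S, theta)$L, oracle, tolerance = 1e-10)
  }
})

test_that("partial symmetric SVT agrees with the full path above N = 200", {
  L0 <- planted_factor(c(90, 80, 80), seed = 3)
  S <- L0 + withr::with_seed(4, {
    X <- matrix(rnorm(250^2, sd = 0.05), 250); (X + t(X)) / 2
  })
  full <- netphase:::svt_sym(S, 5, full_limit = 1000L)
  part <- netphase:::svt_sym(S, 5, full_limit = 10L)
  expect_equal(sort(part$d), sort(full$d), tolerance = 1e-6)
  expect_equal(part$L, full$L, tolerance = 1e-6)
})

test_that("stopping_metric is the printed ratio", {
  A <- matrix(1, 2, 2)
  st0 <- list(L = matrix(0, 2, 2), S = matrix(0, 2, 2))
  expect_equal(stopping_metric(st0, st0), 0)
  # prev zero, curr L with squared norm 2: 2 / (0 + 0 + 1)
  curr <- list(L = matrix(c(1, 0, 0, 1), 2), S = st0$S)
  expect_equal(stopping_metric(st0, curr), 2)
  st1 <- list(L = matrix(rnorm(4), 2), S = matrix(rnorm(4), 2))
  st2 <- list(L = matrix(rnorm(4), 2), S = matrix(rnorm(4), 2))
  expect_gte(stopping_metric(st1, st2), 0)
})

test_that("zero input is a one-sweep fixed point", {
  d <- asalm_decompose(matrix(0, 10, 10), solver_config(alpha = 1))
  expect_true(d$converged)
  expect_equal(d$iterations, 1L)
  expect_equal(d$L, matrix(0, 10, 10))
  expect_equal(d$S, matrix(0, 10, 10))
  expect_equal(d$E, matrix(0, 10, 10))
})

test_that("noise-free planted low-rank inputs are recovered", {
  # the relaxed objective leaves a rank-deterministic Frobenius gap of about
  # sqrt(r)/(2 alpha); noise-free input warrants a large dense-noise weight
  u <- rep(0.8, 50)
  A <- tcrossprod(u)
  d <- asalm_decompose(A, solver_config(alpha = 5, gamma = 1 / sqrt(50)))
  expect_true(d$converged)
  expect_lt(sqrt(sum((d$L - A)^2)) / sqrt(sum(A^2)), 1e-2)
  expect_equal(length(d$singular_values), 1L)
  expect_lt(sum(abs(d$S)), 1e-6)

  for (r in 2:3) {
    L0 <- planted_factor(rep(100 %/% r, r), seed = r)
    d <- asalm_decompose(L0, solver_config(alpha = 5))
    expect_lt(sqrt(sum((d$L - L0)^2)) / sqrt(sum(L0^2)), 1e-2)
    expect_equal(length(d$singular_values), r)
  }
})

test_that("planted sparse support is identified (rank-3 + Bernoulli noise)", {
  L0 <- planted_factor(c(34, 33, 33), seed = 9)
  S0 <- gen_sparse_noise(100, 0.05, seed = 9)
  A <- L0 + S0
  d <- asalm_decompose(A, solver_config(alpha = 2))
  expect_equal(length(d$singular_values), 3L)
  supp_t <- abs(S0) > 0
  supp_p <- abs(d$S) > 1e-3
  jac <- sum(supp_t & supp_p) / sum(supp_t | supp_p)
  expect_gte(jac, 0.8)
})

test_that("iterates stay symmetric and feasible at convergence", {
  sc <- tiny_scenario(seed = 2)
  A <- sc$network$snapshots[[1]]$matrix
  d <- asalm_decompose(A, solver_config(alpha = 0.3, eps = 1e-8))
  for (nm in c("L", "S", "E", "Lambda"))
    expect_identical(d[[nm]], t(d[[nm]]))
  expect_true(d$converged)
  expect_lt(d$residual / sqrt(sum(A^2)), 1e-3)
})

test_that("doubling beta halves both shrinkage thresholds", {
  A <- tiny_scenario(seed = 3)$network$snapshots[[1]]$matrix
  d1 <- suppressWarnings(
    asalm_decompose(A, solver_config(alpha = 0.3, beta = 0.4, max_iter = 5)))
  d2 <- suppressWarnings(
    asalm_decompose(A, solver_config(alpha = 0.3, beta = 0.8, max_iter = 5)))
  expect_equal(d1$thresh_s / 2, d2$thresh_s)
  expect_equal(d1$thresh_l / 2, d2$thresh_l)
})

test_that("decompose_sequence is elementwise-identical to single solves", {
  sc <- tiny_scenario(seed = 4, T_n = 3)
  net <- pad_to_union(sc$network)
  cfg <- solver_config(alpha = 0.3)
  ds <- decompose_sequence(net, cfg)
  expect_length(ds, 3L)
  one <- asalm_decompose(net$snapshots[[2]]$matrix, cfg)
  expect_equal(ds[[2]]$L, one$L)
  # identical snapshots give identical results (determinism)
  reps <- decompose_sequence(rep(list(net$snapshots[[1]]$matrix), 2), cfg)
  expect_identical(reps[[1]]$L, reps[[2]]$L)
  expect_error(decompose_sequence(list(matrix(c(0, 1, 2, 0), 2)), cfg),
               "t = 1")
})
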