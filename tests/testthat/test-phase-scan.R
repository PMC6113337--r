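test_that("window_partition keeps the remainder window", {
  w <- window_partition(200, 7)
  expect_equal(nrow(w), 29L)
  expect_equal(unname(w[29, ]), c(197L, 200L))  # length-4 remainder
  expect_true(all(w[-29, 2] - w[-29, 1] + 1L == 7L))

  expect_equal(unname(window_partition(6, 2)),
               cbind(c(1L, 3L, 5L), c(2L, 4L, 6L)))
  expect_equal(unname(window_partition(5, 5)), cbind(1L, 5L))
  expect_equal(nrow(window_partition(9)), 3L)  # default floor(sqrt(T))
  expect_error(window_partition(5, 0), "positive")
  expect_error(window_partition(5, 6), "exceed")
})

test_that("window_average is the elementwise mean", {
  Ls <- lapply(1:3, function(t) t * diag(2))
  expect_equal(window_average(Ls, c(2, 2)), 2 * diag(2))
  expect_equal(window_average(Ls, c(1, 3)), 2 * diag(2))
  same <- rep(list(matrix(1, 2, 2)), 3)
  expect_equal(window_average(same, c(1, 3)), matrix(1, 2, 2))
  expect_error(window_average(Ls, c(3, 2)), "invalid window")
})

test_that("thresholded_rank counts singular values above h", {
  expect_equal(thresholded_rank(diag(c(5, 3, 0.1)), 1), 2L)
  M <- planted_factor(c(10, 10), seed = 2)
  expect_equal(thresholded_rank(M, 0), qr(M)$rank)
  expect_equal(thresholded_rank(M, max(svd(M)$d) + 1), 0L)
  # nonincreasing in h (property over random symmetric + asymmetric inputs)
  for (seed in 1:6) {
    X <- withr::with_seed(seed, matrix(rnorm(64), 8))
    if (seed %% 2) X <- (X + t(X)) / 2
    hs <- seq(0, 6, by = 0.5)
    r <- vapply(hs, function(h) thresholded_rank(X, h), integer(1))
    expect_true(all(diff(r) <= 0))
  }
})

make_trace <- function(tr, h_grid = seq_len(ncol(tr)), T_n = 2 * nrow(tr)) {
  structure(list(windows = window_partition(T_n, 2), h_grid = h_grid,
                 tr = tr), class = "rank_trace")
}

test_that("select_h picks the widest informative plateau", {
  # plateaus of widths 2 and 4 columns: pick from the width-4
  tr <- cbind(c(9L, 9L, 5L), c(9L, 9L, 5L), c(7L, 6L, 5L),
              c(4L, 4L, 3L), c(4L, 4L, 3L), c(4L, 4L, 3L), c(4L, 4L, 3L))
  h <- select_h(make_trace(tr))
  expect_equal(attr(h, "plateau"), c(4L, 7L))
  expect_equal(as.numeric(h), mean(c(4, 7)))

  # profile changing at every grid point: failure
  tr2 <- cbind(c(5L, 5L), c(4L, 5L), c(4L, 4L), c(3L, 4L))
  expect_error(select_h(make_trace(tr2)), "plateau|constant rank")

  # rank-1-everywhere plateaus are uninformative and never selected
  tr3 <- cbind(c(6L, 3L), c(6L, 3L), c(1L, 1L), c(1L, 1L), c(1L, 1L))
  h3 <- select_h(make_trace(tr3))
  expect_equal(attr(h3, "plateau"), c(1L, 2L))
})

test_that("detect_transitions flags and merges volatile windows", {
  tr <- matrix(c(11L, 11L, 11L, 12L, 7L, 7L), ncol = 1)
  out <- detect_transitions(make_trace(tr, h_grid = 1, T_n = 12), 1)
  expect_equal(nrow(out), 1L)
  expect_equal(unname(out[1, c("first", "last")]), c(4L, 5L))
  expect_equal(unname(out[1, c("start", "end")]), c(7L, 10L))

  const <- matrix(5L, 6, 1)
  expect_equal(nrow(detect_transitions(make_trace(const, 1, 12), 1)), 0L)
})

test_that("scan on a rank-constant sequence reports one segment", {
  L <- planted_factor(c(8, 8), seed = 1)
  rep <- scan_transitions(rep(list(L), 16))
  expect_length(rep$epochs, 0L)
  expect_equal(rep$segments, list(c(1L, 16L)))
})

test_that("scan finds a planted structure change and reverses with time", {
  sc <- tiny_scenario(seed = 7, n = 60, T_n = 24, t_change = 13)
  net <- pad_to_union(sc$network)
  decs <- decompose_sequence(net, solver_config(alpha = 0.5))
  Ls <- lapply(decs, `[[`, "L")
  rep <- scan_transitions(Ls, levels = c(4L, 2L))
  expect_length(rep$epochs, 1L)
  expect_true(epoch_detected(rep$epochs, c(12L, 13L), slack = 1L))

  rev_rep <- scan_transitions(rev(Ls), levels = c(4L, 2L))
  expect_length(rev_rep$epochs, 1L)
  mirrored <- sort(24 + 1 - rev(rev_rep$epochs[[1]]))
  expect_lte(max(abs(mirrored - rep$epochs[[1]])), 2)
})
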