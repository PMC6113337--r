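#' Search grid for the dense-noise weight
#'
#' Evenly spaced values covering the open interval
#' \eqn{(0.5/\sqrt{N+\sqrt{8N}},\ 10/\sqrt{N+\sqrt{8N}})} with the given
#' spacing (default 0.015).
#'
#' @param N Node count (>= 2).
#' @param step Grid spacing (> 0).
#' @return Increasing numeric vector of candidate \eqn{\alpha} values.
#' @export
alpha_grid <- function(N, step = 0.015) {
  if (N < 2) stop("N >= 2 required")
  if (step <= 0) stop("`step` must be positive")
  s <- sqrt(N + sqrt(8 * N))
  lo <- 0.5 / s
  hi <- 10 / s
  if (step > hi - lo)
    stop(sprintf("step %.4g exceeds interval width %.4g", step, hi - lo))
  g <- seq(lo, hi, by = step)
  if (length(g) < 2L) stop("grid must contain at least 2 points")
  g
}

#' Inconsistency between low-rank components at consecutive alpha values
#'
#' \eqn{\|L_a - L_b\|_F / (\|L_a\|_F + 1)}.  The "+1" guards division by
#' zero, paralleling the solver's stopping condition.
#'
#' @param L_a,L_b Matrices of identical shape.
#' @return Nonnegative scalar, zero iff the matrices are equal.
#' @export
inconsistency <- function(L_a, L_b) {
  if (!all(dim(L_a) == dim(L_b))) stop("shape mismatch")
  sqrt(sum((L_a - L_b)^2)) / (sqrt(sum(L_a^2)) + 1)
}

# Numerical rank from the solver's returned singular values: SVT produces
# exact zeros, so counting entries above N * eps * sigma_1 is robust.
numerical_rank <- function(d, n) {
  if (!length(d)) return(0L)
  sum(d > n * .Machine$double.eps * max(d))
}

#' Scan a grid of alpha values over sampled time points
#'
#' Decomposes the sampled snapshots at every grid value and records the rank
#' of the recovered low-rank component and the inconsistency between
#' consecutive grid values.
#'
#' @param net Padded \code{\link{temporal_network}} or list of symmetric
#'   matrices.
#' @param alphas Increasing grid; default \code{\link{alpha_grid}} on the
#'   snapshot size.
#' @param sample_times Time indices to probe; default \code{n_times} evenly
#'   spaced indices.
#' @param n_times Number of evenly spaced sample times (default 20).
#' @param gamma,eps,max_iter Passed to \code{\link{solver_config}};
#'   \code{gamma = NULL} means \eqn{1/\sqrt{N}}.
#' @param step Grid spacing when \code{alphas} is derived automatically.
#' @return An \code{alpha_scan} object: list with \code{alphas},
#'   \code{sample_times}, integer matrix \code{ranks} (time x alpha) and
#'   matrix \code{inconsistencies} (time x consecutive-alpha pairs).
#' @export
alpha_scan <- function(net, alphas = NULL, sample_times = NULL, n_times = 20L,
                       gamma = NULL, eps = 1e-6, max_iter = 500L,
                       step = 0.015) {
  mats <- if (inherits(net, "temporal_network")) {
    if (!isTRUE(net$padded)) stop("pad the network first (pad_to_union)")
    as_matrix_list(net)
  } else net
  Tn <- length(mats)
  n <- nrow(mats[[1L]])
  if (is.null(alphas)) alphas <- alpha_grid(n, step)
  if (is.null(sample_times))
    sample_times <- unique(round(seq(1, Tn, length.out = min(n_times, Tn))))
  ranks <- matrix(NA_integer_, length(sample_times), length(alphas))
  inco <- matrix(NA_real_, length(sample_times), length(alphas) - 1L)
  for (i in seq_along(sample_times)) {
    A <- mats[[sample_times[i]]]
    prevL <- NULL
    for (j in seq_along(alphas)) {
      d <- asalm_decompose(A, solver_config(alpha = alphas[j], gamma = gamma,
                                            eps = eps, max_iter = max_iter))
      ranks[i, j] <- numerical_rank(d$singular_values, n)
      if (!is.null(prevL)) inco[i, j - 1L] <- inconsistency(prevL, d$L)
      prevL <- d$L
    }
  }
  structure(list(alphas = alphas, sample_times = sample_times,
                 ranks = ranks, inconsistencies = inco),
            class = "alpha_scan")
}

#' Select alpha from a scan
#'
#' Finds the widest contiguous run of grid values on which, for every sampled
#' time, the rank of \eqn{L(t)} is constant in \eqn{\alpha}; within that
#' plateau returns the value minimizing the mean inconsistency to its grid
#' neighbours.  Ties (equally wide plateaus, or equal inconsistency) are
#' broken toward larger \eqn{\alpha}.
#'
#' @param scan An \code{alpha_scan} with >= 3 grid values and >= 2 sample
#'   times.
#' @return Selected scalar \eqn{\alpha}, with attributes \code{plateau}
#'   (index range) and \code{alpha_range}.
#' @export
select_alpha <- function(scan) {
  stopifnot(inherits(scan, "alpha_scan"))
  R <- scan$ranks
  if (ncol(R) < 3L || nrow(R) < 2L)
    stop("scan must cover >= 3 alpha values and >= 2 sample times")
  m <- ncol(R)
  # column j starts/extends a plateau if every time's rank matches column j-1
  same <- vapply(seq_len(m - 1L), function(j) all(R[, j] == R[, j + 1L]),
                 logical(1))
  best <- c(0L, 0L)  # start, length (in grid points)
  j <- 1L
  while (j <= m) {
    len <- 1L
    while (j + len - 1L <= m - 1L && same[j + len - 1L]) len <- len + 1L
    if (len >= best[2L]) best <- c(j, len)  # >= ties toward larger alpha
    j <- j + len
  }
  if (best[2L] < 2L)
    stop("no alpha interval of >= 2 grid points with time-wise constant ",
         "ranks; try a finer grid")
  idx <- seq(best[1L], best[1L] + best[2L] - 1L)
  # mean inconsistency of grid point j to its neighbours, within the plateau
  neigh <- vapply(idx, function(j) {
    cols <- intersect(c(j - 1L, j), seq_len(m - 1L))
    mean(scan$inconsistencies[, cols])
  }, numeric(1))
  pick <- idx[max(which(neigh == min(neigh)))]
  structure(scan$alphas[pick],
            plateau = c(idx[1L], idx[length(idx)]),
            alpha_range = range(scan$alphas[idx]))
}
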