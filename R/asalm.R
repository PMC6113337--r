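#' Solver configuration for the low-rank + sparse + dense decomposition
#'
#' Parameters of the per-snapshot problem
#' \deqn{\min \|L\|_* + \gamma \|S\|_1 + \alpha \|E\|_F^2
#'       \quad \mathrm{s.t.}\ A = L + S + E,}
#' solved by the alternating splitting augmented Lagrangian method (ASALM).
#'
#' @param alpha Dense-noise weight \eqn{\alpha > 0}.
#' @param gamma Sparsity weight \eqn{\gamma > 0}.  If \code{NULL}, the
#'   general-purpose default \eqn{1/\sqrt{N}} is used per snapshot.
#' @param beta Augmented-Lagrangian penalty \eqn{\beta > 0}.  If \code{NULL},
#'   \code{\link{default_beta}} is applied per snapshot.
#' @param eps Stopping tolerance \eqn{\varepsilon} for the relative squared
#'   change of \eqn{(L, S)} between sweeps.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @return A \code{solver_config} list.
#' @export
solver_config <- function(alpha, gamma = NULL, beta = NULL,
                          eps = 1e-6, max_iter = 500L) {
  chk <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || x <= 0))
      stop(sprintf("`%s` must be a positive scalar", nm))
  }
  chk(alpha, "alpha"); chk(gamma, "gamma"); chk(beta, "beta"); chk(eps, "eps")
  if (max_iter < 1L) stop("`max_iter` must be >= 1")
  structure(list(alpha = alpha, gamma = gamma, beta = beta,
                 eps = eps, max_iter = as.integer(max_iter)),
            class = "solver_config")
}

#' Default augmented-Lagrangian penalty
#'
#' \eqn{\beta = 0.15 N^2 / \|A\|_1} with \eqn{\|A\|_1 = \sum_{ij} |A_{ij}|}
#' the elementwise \eqn{\ell_1} norm.
#'
#' @param A A \code{\link{weighted_network}} or numeric matrix.
#' @return Scalar \eqn{\beta}.
#' @export
default_beta <- function(A) {
  M <- if (inherits(A, "weighted_network")) A$matrix else A
  l1 <- sum(abs(M))
  if (l1 <= 0) stop("all-zero matrix: beta = 0.15 N^2 / ||A||_1 is undefined")
  0.15 * nrow(M)^2 / l1
}

#' Elementwise soft-thresholding (shrinkage) operator
#'
#' \eqn{\mathrm{sign}(x)\,\max(|x| - \theta, 0)}, the proximal operator of the
#' \eqn{\ell_1} norm; applied elementwise to vectors or matrices.
#'
#' @param x Numeric scalar, vector or matrix.
#' @param theta Nonnegative threshold.
#' @return Object of the same shape as \code{x}.
#' @export
soft_threshold <- function(x, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("`theta` must be a nonnegative scalar")
  sign(x) * pmax(abs(x) - theta, 0)
}

#' Singular value thresholding
#'
#' The proximal operator of the nuclear norm: with \eqn{M = U \Sigma V^T},
#' returns \eqn{U\, \mathrm{soft}(\Sigma, \theta)\, V^T}.  The result has rank
#' equal to the number of singular values exceeding \code{theta}.
#'
#' @param M Numeric matrix with finite entries.
#' @param theta Nonnegative threshold.
#' @return Matrix of the same shape as \code{M}.
#' @export
svt <- function(M, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("`theta` must be a nonnegative scalar")
  if (any(!is.finite(M))) stop("`M` must have finite entries")
  sv <- svd(M)
  d <- pmax(sv$d - theta, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*%
    (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

# --- symmetric SVT used inside the solver -----------------------------------
#
# For symmetric M the SVD is the eigendecomposition up to signs: singular
# values are |lambda_i|.  SVT then shrinks |lambda_i| toward zero, keeping the
# sign.  For N <= full_limit a full LAPACK eigendecomposition is used; above
# that, a randomized subspace iteration computes only the leading eigenpairs
# (by magnitude), growing the rank guess geometrically (start 10, x2) until
# the smallest computed |lambda| falls below the threshold.  Returns the
# thresholded matrix and the surviving "singular values" (shrunk magnitudes).

svt_sym <- function(M, theta, full_limit = 200L, rank_hint = 10L) {
  n <- nrow(M)
  if (n <= full_limit) {
    e <- eigen(M, symmetric = TRUE)
    mag <- pmax(abs(e$values) - theta, 0)
    keep <- mag > 0
    if (!any(keep)) return(list(L = matrix(0, n, n), d = numeric(0)))
    vals <- sign(e$values[keep]) * mag[keep]
    V <- e$vectors[, keep, drop = FALSE]
    return(list(L = V %*% (vals * t(V)), d = mag[keep]))
  }
  k <- max(10L, min(as.integer(rank_hint), n))
  repeat {
    pe <- partial_eigen_sym(M, k)
    if (k >= n || min(abs(pe$values)) < theta) break
    k <- min(2L * k, n)
  }
  keep <- abs(pe$values) > theta
  if (!any(keep)) return(list(L = matrix(0, n, n), d = numeric(0)))
  vals <- sign(pe$values[keep]) * (abs(pe$values[keep]) - theta)
  V <- pe$vectors[, keep, drop = FALSE]
  list(L = V %*% (vals * t(V)), d = abs(vals))
}

# Randomized subspace iteration for the k leading (by magnitude) eigenpairs of
# a symmetric matrix.  Two power steps square the spectrum, so magnitudes
# dominate regardless of sign; oversampling p stabilises the subspace.  The
# Gaussian test matrix is drawn from a private RNG stream so callers' RNG
# state is untouched and results are reproducible.
partial_eigen_sym <- function(M, k, p = 8L, q = 2L) {
  n <- nrow(M)
  kk <- min(n, k + p)
  Om <- withr::with_seed(760613L + n + 131L * k,
                         matrix(stats::rnorm(n * kk), n, kk))
  Y <- M %*% Om
  for (i in seq_len(q)) {
    Y <- qr.Q(qr(Y))
    Y <- M %*% (M %*% Y)
  }
  Q <- qr.Q(qr(Y))
  B <- crossprod(Q, M %*% Q)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(min(k, ncol(Q)))]
  list(values = e$values[ord],
       vectors = Q %*% e$vectors[, ord, drop = FALSE])
}

#' Stopping metric of the ASALM sweep
#'
#' \deqn{\frac{\|L^{q+1}-L^q\|_F^2 + \|S^{q+1}-S^q\|_F^2}
#'            {\|L^q\|_F^2 + \|S^q\|_F^2 + 1}}
#'
#' @param prev,curr Lists with elements \code{L} and \code{S} (consecutive
#'   iterates).
#' @return Nonnegative scalar.
#' @export
stopping_metric <- function(prev, curr) {
  (sum((curr$L - prev$L)^2) + sum((curr$S - prev$S)^2)) /
    (sum(prev$L^2) + sum(prev$S^2) + 1)
}

#' Decompose one snapshot into low-rank + sparse + dense components
#'
#' Runs the alternating splitting augmented Lagrangian method on a single
#' symmetric adjacency matrix.  Per sweep: closed-form dense-noise update,
#' elementwise soft-thresholding for the sparse part, singular value
#' thresholding for the low-rank part, then multiplier ascent
#' \eqn{\Lambda \leftarrow \Lambda + \beta(A - L - S - E)}.  All four matrices
#' are re-symmetrized as \eqn{(X + X^T)/2} after every sweep.  Starts from
#' \eqn{L = S = E = \Lambda = 0}.
#'
#' @param A \code{\link{weighted_network}} or symmetric numeric matrix.
#' @param cfg A \code{\link{solver_config}}.
#' @return An object of class \code{decomposition}: list with matrices
#'   \code{L}, \code{S}, \code{E}, \code{Lambda}, plus \code{iterations},
#'   \code{converged}, \code{residual} (\eqn{\|A-L-S-E\|_F} at exit),
#'   \code{metric} (last stopping-metric value), \code{singular_values} of the
#'   final \code{L}, and the thresholds \code{thresh_s} (\eqn{\gamma/\beta})
#'   and \code{thresh_l} (\eqn{1/\beta}) used.
#' @export
asalm_decompose <- function(A, cfg) {
  M <- if (inherits(A, "weighted_network")) A$matrix else A
  if (!isTRUE(all.equal(M, t(M), tolerance = 0, check.attributes = FALSE)))
    stop("`A` must be exactly symmetric")
  stopifnot(inherits(cfg, "solver_config"))
  n <- nrow(M)
  alpha <- cfg$alpha
  gamma <- if (is.null(cfg$gamma)) 1 / sqrt(n) else cfg$gamma
  if (all(M == 0)) {
    z <- matrix(0, n, n)
    beta0 <- if (is.null(cfg$beta)) NA_real_ else cfg$beta
    return(structure(list(L = z, S = z, E = z, Lambda = z,
                          iterations = 1L, converged = TRUE, residual = 0,
                          metric = 0, singular_values = numeric(0),
                          thresh_s = gamma / beta0, thresh_l = 1 / beta0,
                          alpha = alpha, gamma = gamma, beta = beta0),
                     class = "decomposition"))
  }
  beta <- if (is.null(cfg$beta)) default_beta(M) else cfg$beta

  L <- S <- E <- Lambda <- matrix(0, n, n)
  dvals <- numeric(0)
  conv <- FALSE
  metric <- NA_real_
  it <- 0L
  rank_hint <- 10L
  for (it in seq_len(cfg$max_iter)) {
    L0 <- L; S0 <- S
    G <- M + Lambda / beta
    E <- beta / (2 * alpha + beta) * (G - L - S)
    S <- soft_threshold(G - L - E, gamma / beta)
    sv <- svt_sym(G - S - E, 1 / beta, rank_hint = rank_hint)
    L <- sv$L
    dvals <- sv$d
    rank_hint <- max(10L, length(dvals) + 2L)
    Lambda <- Lambda + beta * (M - L - S - E)
    # re-symmetrize (floating point only; updates preserve symmetry in exact
    # arithmetic)
    L <- (L + t(L)) / 2; S <- (S + t(S)) / 2
    E <- (E + t(E)) / 2; Lambda <- (Lambda + t(Lambda)) / 2
    metric <- stopping_metric(list(L = L0, S = S0), list(L = L, S = S))
    if (metric <= cfg$eps) { conv <- TRUE; break }
  }
  if (!conv)
    warning(sprintf("ASALM did not converge in %d iterations (metric %.3g)",
                    cfg$max_iter, metric))
  structure(list(L = L, S = S, E = E, Lambda = Lambda,
                 iterations = it, converged = conv,
                 residual = sqrt(sum((M - L - S - E)^2)),
                 metric = metric,
                 singular_values = dvals,
                 thresh_s = gamma / beta, thresh_l = 1 / beta,
                 alpha = alpha, gamma = gamma, beta = beta),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition: %d x %d, rank(L) = %d, %d iterations, %s, residual %.3g>\n",
              nrow(x$L), ncol(x$L), length(x$singular_values), x$iterations,
              if (x$converged) "converged" else "NOT converged", x$residual))
  invisible(x)
}

#' Decompose every snapshot of a temporal network
#'
#' Applies \code{\link{asalm_decompose}} independently to each snapshot.
#' Snapshots are independent problems, so results do not depend on evaluation
#' order.
#'
#' @param net A padded \code{\link{temporal_network}} (see
#'   \code{\link{pad_to_union}}), or a plain list of symmetric matrices.
#' @param cfg A \code{\link{solver_config}}.
#' @param progress Print a dot every 10 snapshots.
#' @param components \code{"all"} keeps the full per-snapshot decomposition;
#'   \code{"L"} drops the \code{S}, \code{E} and \code{Lambda} matrices as
#'   each snapshot finishes (scalar diagnostics are kept), bounding memory
#'   for long high-dimensional sequences.
#' @return List of \code{decomposition} objects, one per time index.
#' @export
decompose_sequence <- function(net, cfg, progress = FALSE,
                               components = c("all", "L")) {
  components <- match.arg(components)
  mats <- if (inherits(net, "temporal_network")) {
    if (!isTRUE(net$padded)) stop("pad the network first (pad_to_union)")
    as_matrix_list(net)
  } else net
  out <- vector("list", length(mats))
  for (t in seq_along(mats)) {
    d <- tryCatch(asalm_decompose(mats[[t]], cfg),
                  error = function(e)
                    stop(sprintf("snapshot t = %d: %s", t,
                                 conditionMessage(e)), call. = FALSE))
    if (components == "L") d$S <- d$E <- d$Lambda <- NULL
    out[[t]] <- d
    if (progress && t %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out
}
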