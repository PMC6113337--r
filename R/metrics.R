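#' Modularity of a labeled weighted network
#'
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \Big(A_{ij} - \frac{k_i k_j}{2m}\Big)
#'       \delta(g_i, g_j)}
#' with \eqn{k_i = \sum_j A_{ij}}, \eqn{2m = \sum_{ij} A_{ij}} and
#' \eqn{\delta} the label-equality indicator.  Diagonal entries are included;
#' nodes labeled \code{-1} (noise) form their own \eqn{\delta}-class.  Higher
#' values indicate a better partition.
#'
#' @param net \code{\link{weighted_network}} or symmetric matrix.
#' @param labels Integer community label per node.
#' @return Scalar \eqn{Q \in [-1, 1]}, invariant under uniform rescaling of
#'   the weights.
#' @export
modularity_score <- function(net, labels) {
  A <- if (inherits(net, "weighted_network")) net$matrix else net
  stopifnot(length(labels) == nrow(A))
  two_m <- sum(A)
  if (two_m <= 0) stop("zero total weight: modularity undefined")
  deg <- rowSums(A)
  q <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    q <- q + sum(A[idx, idx]) - sum(deg[idx])^2 / two_m
  }
  q / two_m
}

#' Relative polarization of a community
#'
#' Ratio of the mean within-community-\code{k} edge weight to the mean
#' weight outside all communities:
#' \deqn{P_k = \frac{\sum_{ij \in k} A_{ij}}{N_k^2 \, P_{out}}, \qquad
#'       P_{out} = \frac{\sum_{ij} A_{ij} - \sum_{c}\sum_{ij \in c} A_{ij}}
#'                      {N^2 - \sum_c N_c^2}.}
#' All sums run over ordered pairs including the diagonal, as defined.
#' Equals 1 for exchangeable (constant) weights and is invariant under
#' uniform rescaling.
#'
#' @param net \code{\link{weighted_network}} or symmetric matrix.
#' @param labels Integer community label per node; \code{-1} marks noise
#'   nodes belonging to no community.
#' @param k Community id (default: all communities, returns a named vector).
#' @return Scalar \eqn{P_k >= 0}, or named vector over communities.
#' @export
relative_polarization <- function(net, labels, k = NULL) {
  A <- if (inherits(net, "weighted_network")) net$matrix else net
  stopifnot(length(labels) == nrow(A))
  comms <- setdiff(sort(unique(labels)), -1L)
  if (!length(comms)) stop("no communities in `labels`")
  n <- nrow(A)
  sizes <- vapply(comms, function(c) sum(labels == c), numeric(1))
  within <- vapply(comms, function(c) {
    idx <- labels == c
    sum(A[idx, idx])
  }, numeric(1))
  denom_pairs <- n^2 - sum(sizes^2)
  if (denom_pairs <= 0) stop("N^2 must exceed the sum of squared community sizes")
  p_out <- (sum(A) - sum(within)) / denom_pairs
  if (p_out <= 0) stop("P_out = 0: relative polarization undefined")
  pk <- stats::setNames(within / (sizes^2 * p_out), comms)
  if (is.null(k)) pk else pk[[as.character(k)]]
}

#' Node variation (connection standard deviation)
#'
#' Sample standard deviation of a node's connection weights,
#' \deqn{V_i = \sqrt{\frac{1}{N-1} \sum_j \Big[A_{ij} -
#'       \frac{1}{N}\sum_k A_{ik}\Big]^2}.}
#' As printed, the mean divides by \eqn{N} while the sum of squares divides
#' by \eqn{N - 1}; set \code{consistent = TRUE} for the textbook version
#' (both \eqn{N - 1}, i.e. \code{stats::sd} of the row).  High values
#' indicate strongly aligned (polarized) connection patterns.
#'
#' @param net \code{\link{weighted_network}} or symmetric matrix with
#'   \eqn{N \ge 2}.
#' @param i Node index (default: all nodes, returns a vector).
#' @param consistent Use the consistent sample standard deviation.
#' @return Scalar \eqn{V_i \ge 0}, or vector over nodes.
#' @export
node_variation <- function(net, i = NULL, consistent = FALSE) {
  A <- if (inherits(net, "weighted_network")) net$matrix else net
  n <- ncol(A)
  if (n < 2L) stop("N >= 2 required")
  v <- if (consistent) apply(A, 1L, stats::sd)
  else sqrt(rowSums((A - rowMeans(A))^2) / (n - 1))
  if (is.null(i)) v else v[[i]]
}
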