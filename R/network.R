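#' Weighted network snapshot
#'
#' Wraps a symmetric weighted adjacency matrix together with its node
#' identifiers.  Weights are unitless association strengths, typically in
#' \eqn{[0, 1]}; the diagonal is allowed to be nonzero (self-similarity).
#'
#' @param matrix Square numeric matrix, symmetric with finite entries.
#' @param node_ids Character vector of node identifiers, one per row.  Defaults
#'   to existing dimnames or \code{"v1" ... "vN"}.
#' @return An object of class \code{weighted_network}: a list with elements
#'   \code{matrix} and \code{node_ids}.
#' @export
weighted_network <- function(matrix, node_ids = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  n <- nrow(matrix)
  if (n < 2L || ncol(matrix) != n)
    stop("adjacency matrix must be square with N >= 2")
  if (any(!is.finite(matrix)))
    stop("adjacency matrix must have finite entries")
  if (!isTRUE(all.equal(matrix, t(matrix), tolerance = 0, check.attributes = FALSE)))
    stop("adjacency matrix must be exactly symmetric")
  if (is.null(node_ids)) node_ids <- rownames(matrix)
  if (is.null(node_ids)) node_ids <- paste0("v", seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("`node_ids` must have one entry per node")
  if (anyDuplicated(node_ids)) stop("duplicate node ids within a snapshot")
  dimnames(matrix) <- NULL
  structure(list(matrix = matrix, node_ids = node_ids),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network: %d nodes, mean weight %.4g>\n",
              length(x$node_ids), mean(x$matrix)))
  invisible(x)
}

#' Ordered sequence of network snapshots
#'
#' A temporal network is an ordered list of \code{\link{weighted_network}}
#' snapshots for times \eqn{t = 1, \dots, T}, with a global registry mapping
#' node ids to row indices.  Node sets may differ across snapshots; use
#' \code{\link{pad_to_union}} to cast all snapshots to the union node set
#' before decomposition or scanning.
#'
#' @param snapshots List of \code{weighted_network} objects (or plain
#'   symmetric matrices, which are wrapped).
#' @return An object of class \code{temporal_network}: list with
#'   \code{snapshots}, \code{registry} (named integer vector id -> index),
#'   \code{n_max}, and \code{padded} flag.
#' @export
temporal_network <- function(snapshots) {
  if (!length(snapshots)) stop("T >= 1 snapshot required")
  snapshots <- lapply(snapshots, function(s) {
    if (inherits(s, "weighted_network")) s else weighted_network(s)
  })
  ids <- unique(unlist(lapply(snapshots, `[[`, "node_ids")))
  registry <- stats::setNames(seq_along(ids), ids)
  sizes <- vapply(snapshots, function(s) length(s$node_ids), integer(1))
  structure(list(snapshots = snapshots,
                 registry = registry,
                 n_max = length(ids),
                 padded = all(sizes == length(ids))),
            class = "temporal_network")
}

#' @export
print.temporal_network <- function(x, ...) {
  cat(sprintf("<temporal_network: T = %d, n_max = %d%s>\n",
              length(x$snapshots), x$n_max,
              if (isTRUE(x$padded)) ", padded" else ""))
  invisible(x)
}

#' @export
length.temporal_network <- function(x) length(x$snapshots)

#' Pad all snapshots to the union node set
#'
#' Casts every snapshot to an \eqn{N_{max} \times N_{max}} matrix over the
#' global node registry, inserting all-zero rows/columns for nodes absent at a
#' given time.  A per-time logical presence mask is retained so downstream
#' stages can distinguish absent nodes from isolated ones.
#'
#' @param net A \code{\link{temporal_network}}.
#' @return A padded \code{temporal_network} with an additional element
#'   \code{presence}: a \eqn{T \times N_{max}} logical matrix.
#' @export
pad_to_union <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  ids <- names(net$registry)
  n <- net$n_max
  presence <- matrix(FALSE, length(net$snapshots), n,
                     dimnames = list(NULL, ids))
  snaps <- vector("list", length(net$snapshots))
  for (t in seq_along(net$snapshots)) {
    s <- net$snapshots[[t]]
    idx <- net$registry[s$node_ids]
    presence[t, idx] <- TRUE
    M <- matrix(0, n, n)
    M[idx, idx] <- s$matrix
    snaps[[t]] <- weighted_network(M, ids)
  }
  out <- net
  out$snapshots <- snaps
  out$presence <- presence
  out$padded <- TRUE
  out
}

# Extract the list of adjacency matrices from a temporal network.
as_matrix_list <- function(net) lapply(net$snapshots, `[[`, "matrix")
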