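#' Average low-rank components over a stable segment
#'
#' @param Ls List of equally sized matrices indexed by time.
#' @param segment Integer vector \code{c(start, end)} (inclusive).
#' @return Elementwise mean matrix.
#' @export
segment_average <- function(Ls, segment) window_average(Ls, segment)

#' Spectral clustering of a segment-averaged low-rank matrix
#'
#' Entries are clipped below at 0 to form a similarity matrix, the
#' symmetric-normalized Laplacian embedding into the \code{k} leading
#' eigenvectors is computed, rows are unit-normalized and clustered by
#' k-means (fixed seed, multiple restarts).  Nodes with an all-zero
#' similarity row (absent or fully disconnected) are excluded from the
#' embedding and labeled \code{-1}.
#'
#' @param L_bar Symmetric matrix (e.g. a segment-averaged low-rank
#'   component).
#' @param k Number of communities (>= 1); typically the thresholded rank of
#'   \code{L_bar} at the selected threshold.
#' @param seed Seed for the k-means restarts (recorded for reproducibility).
#' @param nstart Number of k-means restarts.
#' @return Integer label vector in \code{\{-1, 0, ..., k-1\}}.
#' @export
spectral_communities <- function(L_bar, k, seed = 1L, nstart = 20L) {
  n <- nrow(L_bar)
  if (k < 1L) stop("k >= 1 required")
  if (k > n) stop("k exceeds matrix size")
  W <- pmax((L_bar + t(L_bar)) / 2, 0)
  deg <- rowSums(W)
  active <- deg > 0
  labels <- rep(-1L, n)
  na <- sum(active)
  if (na == 0L) return(labels)
  k_eff <- min(k, na)
  Wa <- W[active, active, drop = FALSE]
  dis <- 1 / sqrt(rowSums(Wa))
  Lsym <- dis * t(dis * Wa)          # D^{-1/2} W D^{-1/2}
  e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  U <- e$vectors[, seq_len(k_eff), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  cl <- withr::with_seed(as.integer(seed),
    stats::kmeans(U, centers = k_eff, nstart = nstart, iter.max = 100L))
  labels[active] <- cl$cluster - 1L
  labels
}

#' Optimal matching between predicted and reference labels
#'
#' Solves the rectangular assignment problem maximizing total overlap between
#' predicted clusters and reference communities (exact maximum-weight
#' bipartite matching).  Noise labels (\code{-1}) participate as ordinary
#' classes.
#'
#' @param pred,truth Integer label vectors over the same node set.
#' @return Named list: \code{map} (named integer vector, predicted label ->
#'   matched truth label, unmatched labels absent), \code{overlap} (total
#'   matched count).
#' @export
match_labels <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors must have equal length")
  pl <- sort(unique(pred))
  tl <- sort(unique(truth))
  tab <- table(factor(pred, levels = pl), factor(truth, levels = tl))
  # bipartite graph: predicted classes vs truth classes, edge weight = overlap
  np <- length(pl); nt <- length(tl)
  edges <- which(tab > 0, arr.ind = TRUE)
  if (!nrow(edges)) return(list(map = integer(0), overlap = 0L))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, np), rep(TRUE, nt)),
    edges = as.vector(t(cbind(edges[, 1L], np + edges[, 2L]))))
  igraph::E(g)$weight <- tab[edges]
  m <- igraph::max_bipartite_match(g)
  mt <- m$matching[seq_len(np)]
  matched <- !is.na(mt)
  map <- stats::setNames(tl[mt[matched] - np], pl[matched])
  overlap <- sum(tab[cbind(which(matched), mt[matched] - np)])
  list(map = map, overlap = as.integer(overlap))
}

#' Misclassification rate under optimal label matching
#'
#' \eqn{1 - \mathrm{overlap}/N} where overlap is the total agreement under
#' the optimal one-to-one assignment between predicted and reference labels
#' (noise \code{-1} treated as an ordinary class).  Invariant under
#' relabeling permutations of either argument.
#'
#' @param pred,truth Integer label vectors over the same node set.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
misclassification_rate <- function(pred, truth) {
  1 - match_labels(pred, truth)$overlap / length(truth)
}

#' Score detected communities against planted truth
#'
#' A planted community counts as recovered when its best-matched predicted
#' cluster achieves Jaccard overlap >= 0.5.  The error rate is the
#' misclassification (averaged over time when predictions are per-snapshot)
#' restricted to nodes of recovered communities.  Outlier/noise classes
#' (label \code{-1}) are never counted as planted communities.
#'
#' @param pred Integer label vector, or a list of them (one per time index).
#' @param truth Integer label vector, or a list matching \code{pred};
#'   \code{-1} marks outlier nodes, \code{NA} absent nodes.
#' @return An \code{evaluation_result}: list with \code{recovery_rate},
#'   \code{error_rate}, \code{n_recovered}, \code{n_planted} and named vector
#'   \code{per_community_accuracy}.
#' @export
evaluate_detection <- function(pred, truth) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- rep(list(truth), length(pred))
  if (length(truth) == 1L && length(pred) > 1L)
    truth <- rep(truth, length(pred))
  stopifnot(length(pred) == length(truth))
  per_t <- lapply(seq_along(pred), function(t)
    evaluate_one(pred[[t]], truth[[t]]))
  comm <- sort(unique(unlist(lapply(per_t, function(x) names(x$acc)))))
  acc <- vapply(comm, function(k)
    mean(unlist(lapply(per_t, function(x) x$acc[k])), na.rm = TRUE),
    numeric(1))
  structure(list(
    recovery_rate = mean(vapply(per_t, `[[`, numeric(1), "recovery_rate")),
    error_rate = mean(vapply(per_t, `[[`, numeric(1), "error_rate")),
    n_recovered = vapply(per_t, `[[`, integer(1), "n_recovered"),
    n_planted = per_t[[1L]]$n_planted,
    per_community_accuracy = acc),
    class = "evaluation_result")
}

evaluate_one <- function(pred, truth) {
  keep <- !is.na(truth)
  pred <- pred[keep]; truth <- truth[keep]
  planted <- setdiff(sort(unique(truth)), -1L)
  map <- match_labels(pred, truth)$map
  # truth community -> matched predicted label (inverse of map)
  inv <- stats::setNames(as.integer(names(map)), map)
  jac <- acc <- stats::setNames(rep(0, length(planted)), planted)
  for (k in planted) {
    kk <- as.character(k)
    if (!kk %in% names(inv)) next
    p <- inv[[kk]]
    if (p == -1L) next  # a community matched only by the noise label is lost
    inter <- sum(pred == p & truth == k)
    jac[kk] <- inter / sum(pred == p | truth == k)
    acc[kk] <- inter / sum(truth == k)
  }
  recovered <- names(jac)[jac >= 0.5]
  nodes <- truth %in% as.integer(recovered)
  err <- if (any(nodes)) {
    ok <- vapply(which(nodes), function(i)
      pred[i] == inv[[as.character(truth[i])]], logical(1))
    1 - mean(ok)
  } else 0
  list(recovery_rate = length(recovered) / max(length(planted), 1L),
       error_rate = err,
       n_recovered = length(recovered),
       n_planted = length(planted),
       acc = acc)
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation: recovery %.3f (%s of %d), error rate %.4g>\n",
              x$recovery_rate, paste(x$n_recovered, collapse = "/"),
              x$n_planted, x$error_rate))
  invisible(x)
}
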