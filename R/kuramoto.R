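#' Binary support coupling matrix with exact per-node degree constraints
#'
#' Each node in community \eqn{k} of size \eqn{N_k} receives exactly
#' \code{in_frac * N_k} connections inside its community (built as the
#' in-block complement of a seeded regular graph) and \code{out_degree}
#' connections to nodes outside it (a seeded cross-community perfect
#' matching with repair, for \code{out_degree = 1}).
#'
#' @param sizes Integer community sizes (must make \code{in_frac * N_k} an
#'   integer for every block).
#' @param seed Integer seed.
#' @param in_frac Within-community degree fraction (default \eqn{14/16}).
#' @param out_degree Cross-community degree per node (0 or 1).
#' @return Symmetric binary matrix with zero diagonal, plus attribute
#'   \code{membership} (community id per node, 0-based by block order).
#' @export
gen_support <- function(sizes, seed = 1L, in_frac = 14 / 16,
                        out_degree = 1L) {
  n <- sum(sizes)
  memb <- rep(seq_along(sizes) - 1L, sizes)
  C <- matrix(0L, n, n)
  offset <- 0L
  withr::with_seed(sub_seed(seed, "support-in"), {
    for (b in seq_along(sizes)) {
      nk <- sizes[b]
      din <- in_frac * nk
      if (abs(din - round(din)) > 1e-9)
        stop(sprintf("block %d: in-degree %.3g not an integer", b, din))
      din <- as.integer(round(din))
      if (din > nk - 1L)
        stop(sprintf("block %d: in-degree %d exceeds block size - 1", b, din))
      comp <- nk - 1L - din
      B <- if (comp == 0L) 1L - diag(nk)
      else {
        g <- igraph::sample_k_regular(nk, comp)
        1L - diag(nk) - igraph::as_adjacency_matrix(g, sparse = FALSE)
      }
      idx <- offset + seq_len(nk)
      C[idx, idx] <- B
      offset <- offset + nk
    }
  })
  if (out_degree > 0L) {
    if (out_degree != 1L) stop("only out_degree in {0, 1} is supported")
    pairs <- withr::with_seed(sub_seed(seed, "support-out"),
                              cross_matching(memb))
    C[pairs] <- 1L
    C[pairs[, 2:1, drop = FALSE]] <- 1L
  }
  structure(C, membership = memb)
}

# Random perfect matching on nodes such that every pair crosses community
# boundaries; repaired by pair swaps.  Requires an even node count and no
# community holding more than half the nodes.
cross_matching <- function(comm, max_tries = 200L) {
  n <- length(comm)
  if (n %% 2L) stop("cross matching needs an even node count")
  if (max(table(comm)) > n / 2L)
    stop("a community holds more than half the nodes: out-degree-1 matching unrealizable")
  for (try in seq_len(max_tries)) {
    p <- sample.int(n)
    pairs <- matrix(p, ncol = 2L)
    for (rep in seq_len(50L)) {
      bad <- which(comm[pairs[, 1L]] == comm[pairs[, 2L]])
      if (!length(bad)) return(pairs)
      for (b in bad) {
        j <- sample.int(nrow(pairs), 1L)
        tmp <- pairs[b, 2L]
        pairs[b, 2L] <- pairs[j, 2L]
        pairs[j, 2L] <- tmp
      }
    }
  }
  stop("failed to construct a cross-community matching")
}

#' Two-level hierarchical support matrix
#'
#' \code{n_second} loosely coupled groups each holding
#' \code{n_first / n_second} tightly coupled first-level blocks.  Per node:
#' \code{degrees[1]} connections inside the first-level block (15 = complete
#' block of 16), \code{degrees[2]} to the other blocks of its second-level
#' group (one seeded perfect matching per block pair) and \code{degrees[3]}
#' outside both levels (cross-group matching).
#'
#' @param n_first Number of first-level blocks (default 16).
#' @param block_size Nodes per first-level block (default 16).
#' @param n_second Number of second-level groups (default 4).
#' @param degrees Per-node degrees by level, default \code{c(15, 3, 1)}.
#' @param seed Integer seed.
#' @return Symmetric binary matrix with attributes \code{membership}
#'   (first-level) and \code{membership2} (second-level).
#' @export
gen_support_hierarchical <- function(n_first = 16L, block_size = 16L,
                                     n_second = 4L, degrees = c(15L, 3L, 1L),
                                     seed = 1L) {
  if (n_first %% n_second) stop("n_first must be a multiple of n_second")
  per_group <- n_first / n_second
  if (degrees[1L] != block_size - 1L)
    stop("only complete first-level blocks (degree = block_size - 1) supported")
  if (degrees[2L] != per_group - 1L)
    stop("second-level degree must equal blocks-per-group - 1 (one matching per block pair)")
  n <- n_first * block_size
  memb1 <- rep(seq_len(n_first) - 1L, each = block_size)
  memb2 <- memb1 %/% per_group
  C <- matrix(0L, n, n)
  for (b in seq_len(n_first)) {
    idx <- (b - 1L) * block_size + seq_len(block_size)
    C[idx, idx] <- 1L - diag(block_size)
  }
  withr::with_seed(sub_seed(seed, "support-l2"), {
    for (g in seq_len(n_second) - 1L) {
      blocks <- which(memb1 %/% per_group == g & !duplicated(memb1)) # unused
      bids <- unique(memb1[memb2 == g])
      for (i in seq_along(bids)) for (j in seq_along(bids)) {
        if (i >= j) next
        a <- which(memb1 == bids[i]); b2 <- which(memb1 == bids[j])
        perm <- sample.int(block_size)
        C[cbind(a, b2[perm])] <- 1L
        C[cbind(b2[perm], a)] <- 1L
      }
    }
  })
  pairs <- withr::with_seed(sub_seed(seed, "support-l3"),
                            cross_matching(memb2))
  C[pairs] <- 1L
  C[pairs[, 2:1, drop = FALSE]] <- 1L
  structure(C, membership = memb1, membership2 = memb2)
}

#' Integrate coupled Kuramoto phase oscillators (forward Euler)
#'
#' \deqn{\theta_i \leftarrow \theta_i + \tau\Big(\omega_i +
#'       \kappa \sum_j C_{ij} \sin(\theta_j - \theta_i)\Big)}
#' with natural frequencies \eqn{\omega_i} and binary support \eqn{C}.
#' Multiple replicates (columns of \code{theta0} / \code{omega}) are
#' integrated simultaneously.
#'
#' @param C Symmetric binary coupling support matrix.
#' @param omega Natural frequencies: vector of length \eqn{N} or
#'   \eqn{N \times R} matrix (one column per replicate).
#' @param theta0 Initial phases, same shape as \code{omega}.
#' @param kappa Coupling strength \eqn{\kappa > 0} (0 allowed: decoupled
#'   linear drift).
#' @param tau Euler step \eqn{\tau > 0}.
#' @param steps Number of steps; the trajectory is recorded after every step.
#' @return Array of dim \code{c(steps, N, R)} of phases (radians,
#'   unwrapped).
#' @export
kuramoto_integrate <- function(C, omega, theta0, kappa = 0.25, tau = 0.1,
                               steps = 70L) {
  if (tau <= 0) stop("`tau` must be positive")
  if (is.vector(omega)) omega <- matrix(omega, ncol = 1L)
  if (is.vector(theta0)) theta0 <- matrix(theta0, ncol = 1L)
  stopifnot(all(dim(omega) == dim(theta0)), nrow(omega) == nrow(C))
  n <- nrow(C); R <- ncol(omega)
  out <- array(NA_real_, c(steps, n, R))
  th <- theta0
  for (s in seq_len(steps)) {
    sn <- sin(th); cs <- cos(th)
    drift <- omega + kappa * (cs * (C %*% sn) - sn * (C %*% cs))
    th <- th + tau * drift
    out[s, , ] <- th
  }
  out
}

#' Phase-similarity network
#'
#' \eqn{A_{ij} = \langle |\cos(\theta_i - \theta_j)| \rangle}, averaged over
#' replicates.  Entries lie in \eqn{[0, 1]}, the matrix is symmetric with
#' unit diagonal.
#'
#' @param theta \eqn{N \times R} matrix of phases (one column per replicate)
#'   or a vector (single replicate).
#' @return Symmetric similarity matrix.
#' @export
similarity_network <- function(theta) {
  if (is.vector(theta)) theta <- matrix(theta, ncol = 1L)
  n <- nrow(theta)
  A <- matrix(0, n, n)
  for (r in seq_len(ncol(theta))) {
    cs <- cos(theta[, r]); sn <- sin(theta[, r])
    A <- A + abs(tcrossprod(cs) + tcrossprod(sn))
  }
  A <- A / ncol(theta)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}

#' Kuramoto scenario presets
#'
#' \code{"four-period"}: 256 oscillators over T = 280 snapshots with support
#' switches (community merges 16 -> 7 -> 4 -> 2) at epochs 70, 140, 210 and
#' per-period Euler steps \eqn{\tau} = 0.1, 0.08, 0.05, 0.02.
#' \code{"hierarchical"}: fixed two-level structure (16 first-level / 4
#' second-level communities) over T = 100 at \eqn{\tau} = 0.1.  Frequencies
#' \eqn{\omega_i \sim N(0,1)} and initial phases
#' \eqn{\theta_i(0) \sim \mathrm{Unif}(0, 2\pi)} are drawn once per
#' replicate; phases carry over across period boundaries while the support
#' matrix switches.
#'
#' @param preset \code{"four-period"} or \code{"hierarchical"}.
#' @param seed Integer master seed.
#' @param runs Number of initial-phase replicates averaged in the similarity
#'   (the reference setting uses 40).
#' @param kappa Coupling strength (default 0.25).
#' @return List with \code{network} (padded \code{\link{temporal_network}}
#'   of similarity snapshots) and \code{truth} (per-time membership matrix,
#'   planted epochs, segments, the support matrices and \code{seed}).
#' @export
build_kuramoto_scenario <- function(preset = c("four-period", "hierarchical"),
                                    seed = 1L, runs = 40L, kappa = 0.25) {
  preset <- match.arg(preset)
  n <- 256L
  if (preset == "four-period") {
    merges <- list(
      0:15,
      c(0, 0, 0, 0, 4, 4, 4, 7, 7, 7, 10, 10, 12, 12, 14, 15),
      c(0, 0, 0, 0, 4, 4, 4, 7, 7, 7, 4, 4, 12, 12, 0, 0),
      c(0, 0, 0, 0, 4, 4, 4, 4, 4, 4, 4, 4, 0, 0, 0, 0))
    base <- rep(0:15, each = 16L)
    membs <- lapply(merges, function(m) m[base + 1L])
    supports <- lapply(seq_along(membs), function(p) {
      sizes <- as.integer(table(membs[[p]]))
      # nodes ordered by community for support construction, then mapped back
      ord <- order(membs[[p]], seq_len(n))
      Cb <- gen_support(sizes, seed = sub_seed(seed, "support", p))
      C <- matrix(0L, n, n)
      C[ord, ord] <- Cb
      C
    })
    taus <- c(0.1, 0.08, 0.05, 0.02)
    lens <- rep(70L, 4L)
    epochs <- list(c(70L, 71L), c(140L, 141L), c(210L, 211L))
    segments <- list(c(1L, 70L), c(71L, 140L), c(141L, 210L), c(211L, 280L))
  } else {
    Ch <- gen_support_hierarchical(seed = sub_seed(seed, "support", 1L))
    supports <- list(Ch)
    membs <- list(attr(Ch, "membership"))
    taus <- 0.1
    lens <- 100L
    epochs <- list()
    segments <- list(c(1L, 100L))
  }
  om <- withr::with_seed(sub_seed(seed, "omega"),
                         matrix(stats::rnorm(n * runs), n, runs))
  th <- withr::with_seed(sub_seed(seed, "theta0"),
                         matrix(stats::runif(n * runs, 0, 2 * pi), n, runs))
  T_n <- sum(lens)
  snaps <- vector("list", T_n)
  t0 <- 0L
  for (p in seq_along(lens)) {
    traj <- kuramoto_integrate(supports[[p]], om, th, kappa = kappa,
                               tau = taus[p], steps = lens[p])
    for (s in seq_len(lens[p]))
      snaps[[t0 + s]] <- weighted_network(similarity_network(traj[s, , ]))
    th <- traj[lens[p], , ]  # phases carry over
    t0 <- t0 + lens[p]
  }
  memb_t <- do.call(rbind, lapply(seq_along(lens), function(p)
    matrix(membs[[p]], lens[p], n, byrow = TRUE)))
  net <- temporal_network(snaps)
  net$padded <- TRUE
  list(network = net,
       truth = list(membership = memb_t, epochs = epochs,
                    segments = segments, supports = supports,
                    seed = as.integer(seed)))
}
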