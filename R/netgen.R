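# Deterministic substream seeds: one named stream per generated component so
# that scenarios are reproducible and component draws are independent of
# evaluation order.
sub_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Factor-model generator specification
#'
#' Loadings for members of community \eqn{k} are drawn
#' \eqn{\mathrm{Unif}(r_{in}, 1)}, non-members (including outlier nodes)
#' \eqn{\mathrm{Unif}(0, r_{out})}; a node belongs to community \eqn{k} when
#' its loading exceeds \eqn{r_{in}}.
#'
#' @param r_in,r_out Loading bounds, \eqn{0 \le r_{out} < r_{in} \le 1}.
#' @param p_s Sparse-noise density in \eqn{[0, 1]}.
#' @param r Dense-noise amplitude in \eqn{[0, 1]}.
#' @param seed Integer seed.
#' @export
factor_spec <- function(r_in = 0.6, r_out = 0.4, p_s = 0.1, r = 0.1,
                        seed = 1L) {
  if (!(0 <= r_out && r_out < r_in && r_in <= 1))
    stop("require 0 <= r_out < r_in <= 1")
  if (p_s < 0 || p_s > 1 || r < 0 || r > 1) stop("p_s, r must lie in [0, 1]")
  structure(list(r_in = r_in, r_out = r_out, p_s = p_s, r = r,
                 seed = as.integer(seed)),
            class = c("factor_spec", "model_spec"))
}

#' Stochastic block model specification
#'
#' Within-community edges are \eqn{\mathrm{Bernoulli}(p_c)}, between-community
#' edges absent; the sparse perturbation is categorical with
#' \eqn{P(S_{ij} = \pm 1) = p_{flip}} each and 0 otherwise.
#'
#' @param p_c Within-community edge probability in \eqn{(0, 1]}.
#' @param p_flip Flip probability (default 0.05 each way).
#' @param seed Integer seed.
#' @export
sbm_spec <- function(p_c = 0.3, p_flip = 0.05, seed = 1L) {
  if (p_c <= 0 || p_c > 1) stop("p_c must lie in (0, 1]")
  if (p_flip < 0 || 2 * p_flip > 1) stop("invalid p_flip")
  structure(list(p_c = p_c, p_flip = p_flip, seed = as.integer(seed)),
            class = c("sbm_spec", "model_spec"))
}

#' Weighted stochastic block model specification
#'
#' Within-community weights \eqn{\mathrm{Unif}(1 - ub, 1)}, other weights
#' \eqn{\mathrm{Unif}(0, ub)} (so \code{ub = 0.6} reproduces the
#' \eqn{(0.4, 1)} / \eqn{(0, 0.6)} ranges); signal strength decreases as
#' \code{ub} grows.  Alternatively pass explicit \code{in_range} /
#' \code{out_range}.
#'
#' @param ub Upper bound parameterization in \eqn{[0, 1)}.
#' @param in_range,out_range Explicit weight ranges (override \code{ub}).
#' @param p_s Sparse-noise density.
#' @param r Dense-noise amplitude.
#' @param seed Integer seed.
#' @export
wsbm_spec <- function(ub = 0.6, in_range = NULL, out_range = NULL,
                      p_s = 0, r = 0, seed = 1L) {
  if (is.null(in_range)) in_range <- c(1 - ub, 1)
  if (is.null(out_range)) out_range <- c(0, ub)
  if (mean(in_range) <= mean(out_range))
    stop("within-community range must dominate the between range in mean")
  if (p_s < 0 || p_s > 1 || r < 0 || r > 1) stop("p_s, r must lie in [0, 1]")
  structure(list(in_range = in_range, out_range = out_range,
                 p_s = p_s, r = r, seed = as.integer(seed)),
            class = c("wsbm_spec", "model_spec"))
}

#' Factor-model low-rank component
#'
#' Builds \eqn{L = U U^T} where column \eqn{k} of \eqn{U} carries
#' \eqn{\mathrm{Unif}(r_{in}, 1)} loadings for members of community \eqn{k}
#' and \eqn{\mathrm{Unif}(0, r_{out})} otherwise.  Outlier nodes
#' (membership \code{-1}) draw every loading from the non-member law; absent
#' nodes (\code{NA}) have all-zero loadings.
#'
#' @param membership Integer vector: community id per node (\code{-1}
#'   outlier, \code{NA} absent).
#' @param spec A \code{\link{factor_spec}}.
#' @param seed Seed (default \code{spec$seed}).
#' @return \eqn{N \times N} low-rank matrix.
#' @export
gen_factor_L <- function(membership, spec, seed = spec$seed) {
  comms <- setdiff(sort(unique(membership)), -1L)
  comms <- comms[!is.na(comms)]
  if (!length(comms)) stop("membership defines no community")
  n <- length(membership)
  U <- withr::with_seed(sub_seed(seed, "loadings"), {
    U <- matrix(stats::runif(n * length(comms), 0, spec$r_out), n)
    for (j in seq_along(comms)) {
      idx <- which(!is.na(membership) & membership == comms[j])
      U[idx, j] <- stats::runif(length(idx), spec$r_in, 1)
    }
    U
  })
  U[is.na(membership), ] <- 0
  tcrossprod(U)
}

#' Sparse and dense noise matrices
#'
#' \code{gen_sparse_noise}: \eqn{S = S_1 \bullet S_2} with
#' \eqn{S_1 \sim \mathrm{Bernoulli}(p_s)} and
#' \eqn{S_2 \sim \mathrm{Unif}(-1, 1)}.  \code{gen_dense_noise}:
#' \eqn{E \sim \mathrm{Unif}(-r, r)}.  Both sample the upper triangle
#' (including the diagonal) and mirror, so the result is exactly symmetric.
#'
#' @param N Matrix size.
#' @param p_s Sparse support density.
#' @param r Dense amplitude.
#' @param seed Integer seed.
#' @return Symmetric \eqn{N \times N} matrix.
#' @export
gen_sparse_noise <- function(N, p_s, seed) {
  if (p_s == 0) return(matrix(0, N, N))
  withr::with_seed(sub_seed(seed, "sparse"), {
    m <- N * (N + 1) / 2
    v <- (stats::runif(m) < p_s) * stats::runif(m, -1, 1)
    mirror_upper(v, N)
  })
}

#' @rdname gen_sparse_noise
#' @export
gen_dense_noise <- function(N, r, seed) {
  if (r == 0) return(matrix(0, N, N))
  withr::with_seed(sub_seed(seed, "dense"),
                   mirror_upper(stats::runif(N * (N + 1) / 2, -r, r), N))
}

# categorical +/-1 flip noise for the binary SBM
gen_flip_noise <- function(N, p_flip, seed) {
  withr::with_seed(sub_seed(seed, "flip"), {
    u <- stats::runif(N * (N + 1) / 2)
    v <- (u < p_flip) - (u >= p_flip & u < 2 * p_flip)
    mirror_upper(v, N)
  })
}

# fill a symmetric matrix from an upper-triangle (incl. diagonal) vector
mirror_upper <- function(v, N) {
  M <- matrix(0, N, N)
  ut <- upper.tri(M, diag = TRUE)
  M[ut] <- v
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

#' Projection onto symmetric [0, 1] matrices
#'
#' Symmetrizes as \eqn{(X + X^T)/2} then clips entries to \eqn{[0, 1]} -- the
#' Euclidean projection onto
#' \eqn{\Omega = \{X : 0 \le X_{ij} \le 1,\ X_{ij} = X_{ji}\}}.
#'
#' @param X Finite numeric matrix.
#' @return \code{\link{weighted_network}}-compatible matrix in \eqn{\Omega}.
#' @export
project_omega <- function(X) {
  if (any(!is.finite(X))) stop("`X` must be finite")
  pmin(pmax((X + t(X)) / 2, 0), 1)
}

# per-segment block components -----------------------------------------------

gen_sbm_L <- function(membership, spec, seed = spec$seed) {
  n <- length(membership)
  withr::with_seed(sub_seed(seed, "sbm-L"), {
    L <- matrix(0, n, n)
    for (k in setdiff(sort(unique(membership)), -1L)) {
      if (is.na(k)) next
      idx <- which(!is.na(membership) & membership == k)
      nk <- length(idx)
      B <- mirror_upper(as.numeric(stats::runif(nk * (nk + 1) / 2) < spec$p_c),
                        nk)
      L[idx, idx] <- B
    }
    L
  })
}

gen_wsbm_L <- function(membership, spec, seed = spec$seed) {
  n <- length(membership)
  withr::with_seed(sub_seed(seed, "wsbm-L"), {
    L <- mirror_upper(stats::runif(n * (n + 1) / 2, spec$out_range[1L],
                                   spec$out_range[2L]), n)
    for (k in setdiff(sort(unique(membership)), -1L)) {
      if (is.na(k)) next
      idx <- which(!is.na(membership) & membership == k)
      nk <- length(idx)
      L[idx, idx] <- mirror_upper(stats::runif(nk * (nk + 1) / 2,
                                               spec$in_range[1L],
                                               spec$in_range[2L]), nk)
    }
    L[is.na(membership), ] <- 0
    L[, is.na(membership)] <- 0
    L
  })
}

segment_L <- function(membership, spec, seed) {
  L <- if (inherits(spec, "factor_spec")) gen_factor_L(membership, spec, seed)
  else if (inherits(spec, "sbm_spec")) gen_sbm_L(membership, spec, seed)
  else if (inherits(spec, "wsbm_spec")) gen_wsbm_L(membership, spec, seed)
  else stop("unknown model spec")
  L[is.na(membership), ] <- 0
  L[, is.na(membership)] <- 0
  L
}

#' One SBM snapshot
#'
#' \eqn{A = P_\Omega(L + S)} with \eqn{L} the within-community Bernoulli
#' block component and \eqn{S} the categorical \eqn{\pm 1} flip noise; the
#' output is binary.
#'
#' @param membership Community id per node (\code{-1} outlier, \code{NA}
#'   absent).
#' @param spec An \code{\link{sbm_spec}}.
#' @param seed Seed; the low-rank block and the flip noise use separate
#'   substreams.
#' @param L Optional precomputed block component (reused across a stable
#'   segment).
#' @return Symmetric binary matrix.
#' @export
gen_sbm_A <- function(membership, spec, seed = spec$seed, L = NULL) {
  n <- length(membership)
  if (is.null(L)) L <- segment_L(membership, spec, seed)
  S <- gen_flip_noise(n, spec$p_flip, seed)
  S[is.na(membership), ] <- 0; S[, is.na(membership)] <- 0
  project_omega(L + S)
}

#' One WSBM snapshot
#'
#' \eqn{A = P_\Omega(L + S + E)} with the per-segment uniform block weights
#' \code{L} held fixed and fresh sparse/dense noise each time.
#'
#' @inheritParams gen_sbm_A
#' @param spec A \code{\link{wsbm_spec}}.
#' @return Symmetric matrix with entries in \eqn{[0, 1]}.
#' @export
gen_wsbm_A <- function(membership, spec, seed = spec$seed, L = NULL) {
  n <- length(membership)
  if (is.null(L)) L <- segment_L(membership, spec, seed)
  S <- gen_sparse_noise(n, spec$p_s, seed)
  E <- gen_dense_noise(n, spec$r, seed)
  mask <- is.na(membership)
  S[mask, ] <- 0; S[, mask] <- 0; E[mask, ] <- 0; E[, mask] <- 0
  project_omega(L + S + E)
}

# ---------------------------------------------------------------------------
# scenario presets with planted timelines
# ---------------------------------------------------------------------------

# contiguous membership layout: communities of the given sizes get ids 0.. in
# order, followed by n_outlier outliers (-1) and n_absent absent nodes (NA)
layout_membership <- function(sizes, n_outlier = 0L, n_absent = 0L,
                              ids = NULL) {
  if (is.null(ids)) ids <- seq_along(sizes) - 1L
  c(rep(ids, sizes), rep(-1L, n_outlier), rep(NA_integer_, n_absent))
}

scenario_def <- function(name) {
  third <- function(x) as.integer(round(x / 3))
  switch(name,
    "illustrative" = illustrative_def(
      sizes = c(100L, 100L, 90L, 90L, 80L, 80L, 70L, 70L, 60L, 60L, 50L),
      n_outlier = 50L, n_join = 100L, T_n = 200L,
      trans = list(c(30L, 31L), c(60L, 66L), c(130L, 136L)),
      epochs = list(c(30L, 31L), c(60L, 65L), c(130L, 135L))),
    "illustrative-small" = illustrative_def(
      sizes = c(33L, 33L, 30L, 30L, 27L, 27L, 23L, 23L, 20L, 20L, 17L),
      n_outlier = 17L, n_join = 33L, T_n = 60L,
      trans = list(c(9L, 10L), c(18L, 21L), c(39L, 42L)),
      epochs = list(c(9L, 10L), c(18L, 20L), c(39L, 41L))),
    "three-model" = three_model_def(
      sizes = c(120L, 100L, 100L, 100L, 80L, 80L, 70L, 70L, 70L, 60L, 60L),
      n_outlier = 90L),
    "three-model-small" = three_model_def(
      sizes = c(40L, 33L, 33L, 33L, 27L, 27L, 23L, 23L, 23L, 20L, 20L),
      n_outlier = 30L),
    "wsbm-split" = wsbm_split_def(),
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(c("illustrative", "illustrative-small", "three-model",
                         "three-model-small", "wsbm-split"), collapse = ", ")))
  )
}

illustrative_def <- function(sizes, n_outlier, n_join, T_n, trans, epochs) {
  n_core <- sum(sizes) + n_outlier
  n_max <- n_core + n_join
  m1 <- layout_membership(sizes, n_outlier, n_join)        # joiners absent
  m2 <- m1; m2[(n_core + 1):n_max] <- -1L                  # joiners as outliers
  m3 <- m2
  m3[(n_core + 1):n_max] <- NA_integer_                    # joiners leave
  m3[m3 %in% c(10L)] <- 0L                                 # 10 joins 0
  m3[m3 %in% c(9L)] <- 1L                                  # 9 joins 1
  m3[m3 %in% c(7L, 8L)] <- 6L                              # 7, 8 join 6
  m4 <- m2                                                 # revert, then:
  m4[m4 == 8L] <- -1L                                      # 8 disintegrates
  i1 <- which(m4 == 1L); m4[i1[seq_len(length(i1) %/% 2)]] <- 11L  # 1 splits
  i2 <- which(m4 == 2L); m4[i2[seq_len(length(i2) %/% 2)]] <- 12L  # 2 splits
  seg_bounds <- list(c(1L, trans[[1L]][1L]),
                     c(trans[[1L]][2L], trans[[2L]][1L]),
                     c(trans[[2L]][2L], trans[[3L]][1L]),
                     c(trans[[3L]][2L], T_n))
  list(T_n = T_n, n_max = n_max,
       memberships = list(m1, m2, m3, m4),
       transitions = trans, epochs = epochs, segments = seg_bounds)
}

three_model_def <- function(sizes, n_outlier) {
  m1 <- layout_membership(sizes, n_outlier)
  m2 <- m1; m2[m2 == 10L] <- 0L; m2[m2 == 9L] <- 1L
  m3 <- m2; m3[m3 %in% c(7L, 8L)] <- 6L
  list(T_n = 30L, n_max = length(m1),
       memberships = list(m1, m2, m3),
       transitions = list(c(9L, 10L), c(19L, 20L)),
       epochs = list(c(10L, 10L), c(20L, 20L)),
       segments = list(c(1L, 9L), c(10L, 19L), c(20L, 30L)))
}

wsbm_split_def <- function() {
  m1 <- layout_membership(c(200L, 150L, 100L, 50L))
  m2 <- m1
  i0 <- which(m2 == 0L)
  m2[i0[126:200]] <- 4L                                    # 200 -> 125 + 75
  list(T_n = 40L, n_max = 500L,
       memberships = list(m1, m2),
       transitions = list(c(20L, 21L)),
       epochs = list(c(21L, 21L)),
       segments = list(c(1L, 20L), c(21L, 40L)))
}

# membership and migration mask for every t
membership_timeline <- function(def) {
  M <- matrix(NA_integer_, def$T_n, def$n_max)
  mig <- vector("list", def$T_n)
  n_seg <- length(def$memberships)
  for (m in seq_len(n_seg)) {
    lo <- if (m == 1L) 1L else def$transitions[[m - 1L]][2L]
    hi <- if (m == n_seg) def$T_n else def$transitions[[m - 1L + 1L]][1L]
    for (t in lo:hi) M[t, ] <- def$memberships[[m]]
  }
  # progressive steps strictly inside each transition
  for (m in seq_len(n_seg - 1L)) {
    tr <- def$transitions[[m]]
    steps <- seq(tr[1L] + 1L, tr[2L] - 1L)
    if (!length(steps) || tr[2L] - tr[1L] <= 1L) next
    old <- def$memberships[[m]]; new <- def$memberships[[m + 1L]]
    changed <- which(xor(is.na(old), is.na(new)) |
                       (!is.na(old) & !is.na(new) & old != new))
    e <- length(steps)
    for (s in seq_along(steps)) {
      k <- ceiling(s / e * length(changed))
      moved <- changed[seq_len(k)]
      mm <- old; mm[moved] <- new[moved]
      M[steps[s], ] <- mm
      mig[[steps[s]]] <- moved
    }
  }
  list(membership = M, migrated = mig)
}

#' Build a preset temporal-network scenario with planted ground truth
#'
#' Available presets: \code{"illustrative"} (N = 900 growing to 1000,
#' T = 200, four stable periods with 11/11/7/12 communities and transitions
#' at 30-31, 60-65, 130-135, including a 100-node join/leave),
#' \code{"illustrative-small"} (the same four-segment design proportionally
#' scaled to N = 300 + 33 joining nodes, T = 60, transitions 9-10, 18-20,
#' 39-41), \code{"three-model"} (T = 30, N = 1000, community counts 11/9/7,
#' changes at t = 10 and 20), \code{"three-model-small"} (sizes scaled to
#' N = 332) and \code{"wsbm-split"} (N = 500, T = 40, a size-200 community
#' splitting into 125 + 75 at t = 21).
#'
#' The low-rank component is drawn once per stable segment and held fixed;
#' sparse and dense noise are redrawn at every snapshot.  During multi-step
#' transitions, affected nodes migrate progressively to the new structure (a
#' pair of nodes carries the new segment's weight once both have migrated).
#'
#' @param name Preset id.
#' @param seed Integer master seed; all substreams derive from it.
#' @param model A \code{model_spec} (\code{\link{factor_spec}},
#'   \code{\link{sbm_spec}} or \code{\link{wsbm_spec}}).  Defaults:
#'   factor model for the illustrative presets, WSBM for
#'   \code{"wsbm-split"}, factor for the three-model presets.
#' @return List with \code{network} (a \code{\link{temporal_network}} whose
#'   snapshots contain only the nodes present at each time) and \code{truth}
#'   (list: per-time \code{membership} matrix with \code{-1} = outlier,
#'   \code{NA} = absent; planted \code{epochs}; stable \code{segments};
#'   \code{model}; \code{seed}).
#' @export
build_scenario <- function(name, seed = 1L, model = NULL) {
  def <- scenario_def(name)
  if (is.null(model)) {
    model <- if (name == "wsbm-split") wsbm_spec(seed = seed)
    else factor_spec(seed = seed)
  }
  tl <- membership_timeline(def)
  segs_L <- lapply(seq_along(def$memberships), function(m)
    segment_L(def$memberships[[m]], model, sub_seed(seed, "segment", m)))
  ids <- paste0("v", seq_len(def$n_max))
  snaps <- vector("list", def$T_n)
  for (t in seq_len(def$T_n)) {
    memb <- tl$membership[t, ]
    seg_i <- segment_index(def, t)
    L <- segs_L[[seg_i$m]]
    if (!is.null(tl$migrated[[t]])) {
      mv <- tl$migrated[[t]]
      Lnew <- segs_L[[seg_i$m + 1L]]
      L[mv, mv] <- Lnew[mv, mv]
      # nodes absent in the hybrid must stay zero
      L[is.na(memb), ] <- 0; L[, is.na(memb)] <- 0
    }
    A <- snapshot_A(memb, L, model, sub_seed(seed, "t", t))
    present <- !is.na(memb)
    snaps[[t]] <- weighted_network(A[present, present, drop = FALSE],
                                   ids[present])
  }
  list(network = temporal_network(snaps),
       truth = list(membership = tl$membership, epochs = def$epochs,
                    segments = def$segments, model = model,
                    node_ids = ids, seed = as.integer(seed)))
}

# stable segment index governing time t (during a transition: the old one)
segment_index <- function(def, t) {
  for (m in rev(seq_along(def$segments))) {
    if (t >= def$segments[[m]][1L]) {
      in_trans <- m < length(def$segments) &&
        t > def$transitions[[m]][1L] && t < def$transitions[[m]][2L]
      return(list(m = m, in_transition = in_trans))
    }
  }
  # t lies strictly inside transition m -> m+1
  for (m in seq_along(def$transitions)) {
    tr <- def$transitions[[m]]
    if (t > tr[1L] && t < tr[2L]) return(list(m = m, in_transition = TRUE))
  }
  stop("time index outside scenario")
}

snapshot_A <- function(membership, L, model, seed) {
  n <- length(membership)
  mask <- is.na(membership)
  if (inherits(model, "sbm_spec")) {
    S <- gen_flip_noise(n, model$p_flip, seed)
    S[mask, ] <- 0; S[, mask] <- 0
    project_omega(L + S)
  } else {
    S <- gen_sparse_noise(n, model$p_s, seed)
    E <- gen_dense_noise(n, model$r, seed)
    S[mask, ] <- 0; S[, mask] <- 0; E[mask, ] <- 0; E[, mask] <- 0
    project_omega(L + S + E)
  }
}
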