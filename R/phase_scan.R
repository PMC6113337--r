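#' Partition 1..T into consecutive windows
#'
#' Consecutive half-open index intervals of length \code{w}; if \code{T_n}
#' is not a multiple of \code{w}, the final shorter remainder window is kept
#' (dropping it would blind the scanner to changes near \eqn{T}).
#'
#' @param T_n Number of time points.
#' @param w Window length, \eqn{1 \le w \le T}.  Default
#'   \eqn{\lfloor\sqrt{T}\rfloor}.
#' @return A two-column integer matrix with columns \code{start}, \code{end}
#'   (inclusive).
#' @export
window_partition <- function(T_n, w = floor(sqrt(T_n))) {
  if (w <= 0) stop("`w` must be positive")
  if (w > T_n) stop("`w` must not exceed T")
  starts <- seq(1L, T_n, by = as.integer(w))
  cbind(start = starts, end = pmin(starts + as.integer(w) - 1L, T_n))
}

#' Average matrices over a window
#'
#' @param Ls List of equally sized matrices indexed by time.
#' @param window Integer vector \code{c(start, end)} (inclusive).
#' @return Elementwise mean matrix.
#' @export
window_average <- function(Ls, window) {
  idx <- seq(window[1L], window[2L])
  if (!length(idx) || window[1L] < 1L || window[2L] > length(Ls) ||
      window[2L] < window[1L])
    stop("invalid window")
  Reduce(`+`, Ls[idx]) / length(idx)
}

#' Thresholded rank
#'
#' Number of singular values of \code{M} exceeding \code{h}; the effective
#' number of communities encoded by a (window- or segment-averaged) low-rank
#' matrix.
#'
#' @param M Numeric matrix (symmetric matrices use the eigendecomposition:
#'   singular values are absolute eigenvalues).
#' @param h Nonnegative threshold.
#' @return Integer count.
#' @export
thresholded_rank <- function(M, h) {
  if (h < 0) stop("`h` must be nonnegative")
  d <- singular_values_sym(M)
  # numerical-rank floor so that h = 0 returns the numerical rank
  sum(d > max(h, nrow(M) * .Machine$double.eps * max(d, 0)))
}

# Singular values of a matrix; symmetric fast path via eigen.
singular_values_sym <- function(M) {
  if (isTRUE(all.equal(M, t(M), check.attributes = FALSE)))
    abs(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  else svd(M, nu = 0, nv = 0)$d
}

#' Thresholded-rank trace over windows and thresholds
#'
#' @param Ls List of matrices (typically recovered low-rank components).
#' @param windows Window matrix from \code{\link{window_partition}}.
#' @param h_grid Increasing vector of thresholds.  Default: 30 log-spaced
#'   values between 0.1 and \eqn{\sigma_1} of the global mean of \code{Ls}.
#' @return A \code{rank_trace} object: list with \code{windows},
#'   \code{h_grid} and integer matrix \code{tr} (window x threshold),
#'   nonincreasing along each row.
#' @export
rank_trace <- function(Ls, windows, h_grid = NULL) {
  if (is.null(h_grid)) h_grid <- default_h_grid(Ls)
  avg <- lapply(seq_len(nrow(windows)), function(i)
    window_average(Ls, windows[i, ]))
  sv <- lapply(avg, singular_values_sym)
  tr <- t(vapply(sv, function(d) vapply(h_grid, function(h) sum(d > h),
                                        integer(1)),
                 integer(length(h_grid))))
  structure(list(windows = windows, h_grid = h_grid, tr = tr),
            class = "rank_trace")
}

default_h_grid <- function(Ls, n_h = 60L) {
  s1 <- max(singular_values_sym(Reduce(`+`, Ls) / length(Ls)))
  exp(seq(log(0.1), log(max(s1, 0.2)), length.out = n_h))
}

#' Select the rank threshold from a trace
#'
#' Finds the widest contiguous run of grid thresholds over which the
#' per-window rank profile (the vector of thresholded ranks over windows) is
#' unchanged, and returns the midpoint of that run; ties are broken toward
#' the lower interval.
#'
#' @param trace A \code{\link{rank_trace}}.
#' @return Selected threshold \code{h} with attributes \code{h_range} and
#'   \code{plateau} (grid index range).
#' @export
select_h <- function(trace) {
  stopifnot(inherits(trace, "rank_trace"))
  tr <- trace$tr
  m <- ncol(tr)
  if (m < 2L) stop("h grid must contain >= 2 values")
  # thresholds so large that no window retains more than the single leading
  # direction carry no community information (the thresholded rank is meant
  # to count effective communities); exclude them from plateau search
  informative <- apply(tr, 2L, max) >= 2L
  same <- vapply(seq_len(m - 1L), function(j)
    informative[j] && informative[j + 1L] && all(tr[, j] == tr[, j + 1L]),
    logical(1))
  best <- c(0L, 1L)
  j <- 1L
  while (j <= m) {
    len <- 1L
    while (j + len - 1L <= m - 1L && same[j + len - 1L]) len <- len + 1L
    if (len > best[2L]) best <- c(j, len)  # strict: ties toward lower h
    j <- j + len
  }
  if (best[2L] < 2L)
    stop("no h interval spanning >= 2 grid points with a constant rank profile")
  idx <- seq(best[1L], best[1L] + best[2L] - 1L)
  hr <- range(trace$h_grid[idx])
  structure(mean(hr), h_range = hr, plateau = c(idx[1L], idx[length(idx)]))
}

#' Flag candidate transition windows
#'
#' A window is volatile when its thresholded rank at \code{h} differs from
#' that of the preceding window; consecutive volatile windows are merged into
#' one candidate region.
#'
#' @param trace A \code{\link{rank_trace}}.
#' @param h Threshold; the nearest grid value is used.
#' @return Integer matrix with columns \code{first}, \code{last} (window
#'   indices) and \code{start}, \code{end} (snapshot indices), one row per
#'   candidate region; zero rows when the trace is constant.
#' @export
detect_transitions <- function(trace, h) {
  stopifnot(inherits(trace, "rank_trace"))
  j <- which.min(abs(trace$h_grid - h))
  r <- trace$tr[, j]
  flag <- c(FALSE, diff(r) != 0)
  regions <- flag_runs(flag)
  if (!nrow(regions))
    return(cbind(first = integer(0), last = integer(0),
                 start = integer(0), end = integer(0)))
  cbind(first = regions[, 1L], last = regions[, 2L],
        start = trace$windows[regions[, 1L], 1L],
        end = trace$windows[regions[, 2L], 2L])
}

# maximal runs of TRUE -> matrix(start, end)
flag_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# Trim trailing "settling" windows from a flagged run: the last flagged
# window is dropped while its rank equals the stable rank right after the
# run (it was flagged only because it differs from the mixed window before
# it, not because it straddles the change).
trim_region <- function(r, first, last) {
  if (last < length(r)) {
    after <- r[last + 1L]
    while (last > first && r[last] == after) last <- last - 1L
  }
  c(first, last)
}

#' Scan a low-rank sequence for phase-transition epochs
#'
#' Runs the full thresholded-rank scanning strategy: partition \code{1..T}
#' into windows of the coarsest level, average the low-rank components within
#' each window, select a threshold \code{h} from the plateau of the rank
#' profile, flag volatile windows, then recursively zoom into a neighbourhood
#' (one coarse window on each side) of every candidate region with the next
#' smaller window length.  The threshold selected at the coarsest level is
#' reused at finer levels.
#'
#' @param Ls List of equally sized matrices (recovered low-rank components).
#' @param levels Strictly decreasing window lengths; default
#'   \eqn{(\lfloor\sqrt{T}\rfloor,\ \max(2, \lfloor T^{1/4}\rfloor),\ 2)}.
#' @param h Rank threshold; default selected by \code{\link{select_h}} at the
#'   coarsest level.
#' @param h_grid Threshold grid used when selecting \code{h}.
#' @return A \code{transition_report}: list with \code{epochs} (list of
#'   closed 1-based intervals \code{c(lo, hi)}), \code{segments} (stable
#'   intervals between/around them), \code{h_selected}, \code{h_range},
#'   \code{window_lengths}, and \code{traces} (the coarse-level
#'   \code{rank_trace}).
#' @export
scan_transitions <- function(Ls, levels = NULL, h = NULL, h_grid = NULL) {
  T_n <- length(Ls)
  if (is.null(levels)) {
    levels <- unique(pmax(2L, c(floor(sqrt(T_n)),
                                floor(T_n^(1 / 4)), 2L)))
    levels <- sort(levels, decreasing = TRUE)
  }
  if (any(diff(levels) >= 0)) stop("`levels` must be strictly decreasing")
  w0 <- levels[1L]
  coarse <- rank_trace(Ls, window_partition(T_n, w0), h_grid)
  h_range <- NULL
  if (is.null(h)) {
    h <- tryCatch(select_h(coarse),
                  error = function(e)
                    stop(sprintf("level w=%d: %s", w0, conditionMessage(e)),
                         call. = FALSE))
    h_range <- attr(h, "h_range")
    h <- as.numeric(h)
  }
  epochs <- refine_regions(Ls, coarse, h, levels, 1L)
  segments <- complement_intervals(epochs, T_n)
  structure(list(epochs = epochs, segments = segments,
                 h_selected = h, h_range = h_range,
                 window_lengths = levels, traces = coarse),
            class = "transition_report")
}

# Recursive zoom: detect candidate regions at this level; at the finest
# level return trimmed regions as epochs, otherwise rescan each region's
# neighbourhood with the next smaller window.
refine_regions <- function(Ls, trace, h, levels, level_i) {
  w <- levels[level_i]
  cand <- detect_transitions(trace, h)
  if (!nrow(cand)) return(list())
  j <- which.min(abs(trace$h_grid - h))
  r <- trace$tr[, j]
  out <- list()
  for (i in seq_len(nrow(cand))) {
    if (level_i == length(levels)) {
      tr_reg <- trim_region(r, cand[i, "first"], cand[i, "last"])
      out[[length(out) + 1L]] <- c(trace$windows[tr_reg[1L], 1L],
                                   trace$windows[tr_reg[2L], 2L])
    } else {
      lo <- max(1L, cand[i, "start"] - w)
      hi <- min(length(Ls), cand[i, "end"] + w)
      wn <- levels[level_i + 1L]
      sub <- rank_trace(Ls[lo:hi], window_partition(hi - lo + 1L, wn),
                        trace$h_grid)
      sub$windows <- sub$windows + lo - 1L  # back to absolute indices
      out <- c(out, refine_regions(Ls, sub, h, levels, level_i + 1L))
    }
  }
  merge_intervals(out)
}

merge_intervals <- function(ivs) {
  if (!length(ivs)) return(list())
  ivs <- ivs[order(vapply(ivs, `[`, numeric(1), 1L))]
  out <- list(ivs[[1L]])
  for (iv in ivs[-1L]) {
    last <- out[[length(out)]]
    if (iv[1L] <= last[2L] + 1L)
      out[[length(out)]] <- c(last[1L], max(last[2L], iv[2L]))
    else out[[length(out) + 1L]] <- iv
  }
  out
}

complement_intervals <- function(epochs, T_n) {
  if (!length(epochs)) return(list(c(1L, T_n)))
  segs <- list()
  pos <- 1L
  for (e in epochs) {
    if (e[1L] > pos) segs[[length(segs) + 1L]] <- c(pos, e[1L] - 1L)
    pos <- e[2L] + 1L
  }
  if (pos <= T_n) segs[[length(segs) + 1L]] <- c(pos, T_n)
  segs
}

#' @export
print.transition_report <- function(x, ...) {
  ep <- if (length(x$epochs))
    paste(vapply(x$epochs, function(e)
      if (e[1L] == e[2L]) as.character(e[1L]) else paste0(e[1L], "-", e[2L]),
      character(1)), collapse = ", ")
  else "none"
  cat(sprintf("<transition_report: %d epoch(s) [%s], h = %.3g, levels = %s>\n",
              length(x$epochs), ep, x$h_selected,
              paste(x$window_lengths, collapse = ",")))
  invisible(x)
}
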