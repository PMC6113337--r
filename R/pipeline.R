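#' Pipeline configuration
#'
#' Fully-resolved parameters of an end-to-end run; serialized as JSON next
#' to every run's outputs.
#'
#' @param input Input path (mtx-dir or tsv), or \code{NULL} when a network
#'   object is passed to \code{\link{run_pipeline}} directly.
#' @param format Input format for \code{input}.
#' @param alpha Dense-noise weight; \code{NULL} selects it by
#'   \code{\link{select_alpha}} on a grid scan.
#' @param gamma Sparsity weight; \code{NULL} means \eqn{1/\sqrt{N}}.
#' @param beta,eps,max_iter Solver parameters (see
#'   \code{\link{solver_config}}).
#' @param levels Window lengths for \code{\link{scan_transitions}};
#'   \code{NULL} for the default pyramid.
#' @param h Rank threshold; \code{NULL} selects it from the plateau.
#' @param tune_times,tune_step Sample-time count and grid step for the alpha
#'   scan when \code{alpha} is \code{NULL}.
#' @param cluster_seed Seed for the spectral-clustering k-means restarts.
#' @param out Output directory; \code{NULL} for in-memory results only.
#' @return A \code{run_config} list.
#' @export
run_config <- function(input = NULL, format = "mtx-dir", alpha = NULL,
                       gamma = NULL, beta = NULL, eps = 1e-6,
                       max_iter = 500L, levels = NULL, h = NULL,
                       tune_times = 20L, tune_step = 0.015,
                       cluster_seed = 1L, out = NULL) {
  structure(list(input = input, format = format, alpha = alpha,
                 gamma = gamma, beta = beta, eps = eps,
                 max_iter = as.integer(max_iter), levels = levels, h = h,
                 tune_times = as.integer(tune_times), tune_step = tune_step,
                 cluster_seed = as.integer(cluster_seed), out = out),
            class = "run_config")
}

#' Run the full detection pipeline
#'
#' Decompose every snapshot, select tuning parameters where unset, scan for
#' phase-transition epochs, average the low-rank components over the stable
#' segments and extract per-segment communities by spectral clustering, then
#' compute summary metrics.  Deterministic given the seeds in \code{cfg}.
#'
#' @param net A \code{\link{temporal_network}} (padded or not), or
#'   \code{NULL} to read from \code{cfg$input}.
#' @param cfg A \code{\link{run_config}}.
#' @return A \code{pipeline_result} list: \code{report}
#'   (\code{transition_report}), \code{decompositions}, \code{alpha},
#'   \code{segments} (per-segment list with \code{interval}, \code{L_bar},
#'   \code{k}, \code{labels}), \code{metrics} (per-segment modularity and
#'   relative polarization), \code{node_ids} and \code{config}.  When
#'   \code{cfg$out} is set, artifacts (report.json, labels.csv, metrics.csv,
#'   config.json, decompositions) are also written there.
#' @export
run_pipeline <- function(net = NULL, cfg = run_config()) {
  if (is.null(net)) {
    if (is.null(cfg$input)) stop("no input: pass a network or set cfg$input")
    net <- read_temporal(cfg$input, cfg$format)
  }
  if (length(net$snapshots) < 2L) stop("empty or degenerate input")
  if (!isTRUE(net$padded) || is.null(net$presence)) net <- pad_to_union(net)
  mats <- as_matrix_list(net)
  n <- net$n_max

  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, nm) {
    timings[nm] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  alpha <- cfg$alpha
  tuning <- NULL
  if (is.null(alpha)) {
    t0 <- tic()
    tuning <- alpha_scan(mats, n_times = cfg$tune_times, gamma = cfg$gamma,
                         eps = cfg$eps, max_iter = cfg$max_iter,
                         step = cfg$tune_step)
    alpha <- as.numeric(select_alpha(tuning))
    toc(t0, "tune_alpha")
  }
  scfg <- solver_config(alpha = alpha, gamma = cfg$gamma, beta = cfg$beta,
                        eps = cfg$eps, max_iter = cfg$max_iter)
  t0 <- tic()
  decs <- decompose_sequence(mats, scfg)
  toc(t0, "decompose")
  Ls <- lapply(decs, `[[`, "L")
  t0 <- tic()
  report <- scan_transitions(Ls, levels = cfg$levels, h = cfg$h)
  toc(t0, "scan")
  h <- report$h_selected

  t0 <- tic()
  segments <- lapply(report$segments, function(seg) {
    L_bar <- segment_average(Ls, seg)
    k <- max(1L, thresholded_rank(L_bar, h))
    labels <- spectral_communities(L_bar, k, seed = cfg$cluster_seed)
    # nodes absent throughout the segment are noise by definition
    absent <- colSums(net$presence[seg[1L]:seg[2L], , drop = FALSE]) == 0
    labels[absent] <- -1L
    list(interval = seg, L_bar = L_bar, k = k, labels = labels)
  })
  toc(t0, "cluster")

  metrics <- lapply(segments, function(s) {
    A_bar <- segment_average(mats, s$interval)
    has_comm <- any(s$labels >= 0L)
    list(interval = s$interval, k = s$k,
         modularity = if (sum(A_bar) > 0) modularity_score(A_bar, s$labels)
                      else NA_real_,
         polarization = if (has_comm)
           tryCatch(relative_polarization(A_bar, s$labels),
                    error = function(e) NULL))
  })

  res <- structure(list(report = report, decompositions = decs,
                        alpha = alpha, tuning = tuning, segments = segments,
                        metrics = metrics, node_ids = names(net$registry),
                        timings = timings,
                        n_converged = sum(vapply(decs, `[[`, logical(1),
                                                 "converged")),
                        config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$out)) write_pipeline(res, cfg$out)
  res
}

write_pipeline <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rep <- res$report
  jsonlite::write_json(
    list(h = rep$h_selected, h_range = rep$h_range,
         levels = rep$window_lengths, alpha = res$alpha,
         epochs = lapply(rep$epochs, as.integer),
         segments = lapply(rep$segments, as.integer),
         trace = list(windows = unname(rep$traces$windows),
                      h_grid = rep$traces$h_grid, tr = rep$traces$tr)),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
  lab <- do.call(rbind, lapply(res$segments, function(s)
    data.frame(segment_start = s$interval[1L], segment_end = s$interval[2L],
               node_id = res$node_ids, label = s$labels,
               row.names = NULL)))
  utils::write.table(lab, file.path(out, "labels.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  met <- do.call(rbind, lapply(res$metrics, function(m) {
    pol <- m$polarization
    data.frame(segment_start = m$interval[1L], segment_end = m$interval[2L],
               k = m$k, modularity = m$modularity,
               community = if (length(pol)) names(pol) else NA,
               polarization = if (length(pol)) unname(pol) else NA,
               row.names = NULL)
  }))
  utils::write.table(met, file.path(out, "metrics.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(timings_sec = as.list(res$timings),
         snapshots_converged = res$n_converged,
         snapshots_total = length(res$decompositions)),
    file.path(out, "log.json"), auto_unbox = TRUE, digits = NA)
  cfgj <- res$config
  cfgj$levels <- res$report$window_lengths
  cfgj$h <- res$report$h_selected
  cfgj$alpha <- res$alpha
  jsonlite::write_json(cfgj[!vapply(cfgj, is.null, logical(1))],
                       file.path(out, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  write_decompositions(res$decompositions, file.path(out, "decompositions"))
  invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  ks <- vapply(x$segments, `[[`, integer(1), "k")
  cat(sprintf("  alpha = %.4g; per-segment community counts: %s\n",
              x$alpha, paste(ks, collapse = ", ")))
  invisible(x)
}
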