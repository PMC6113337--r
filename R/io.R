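#' Read a temporal network from disk
#'
#' Two plain-text formats are supported.  \code{"mtx-dir"}: one Matrix
#' Market file per time index (files matching \code{*.mtx}, taken in
#' lexicographic order); an optional sidecar \code{<name>.nodes} file lists
#' node ids, one per line (default \code{"v1" ...}).  \code{"tsv"}: a
#' 4-column temporal edge list with header \code{t  i  j  w} (1-based time,
#' undirected edges listed once; listing both orientations with conflicting
#' weights is an error).
#'
#' @param path Directory (mtx-dir) or file (tsv).
#' @param format \code{"mtx-dir"} or \code{"tsv"}.
#' @return A \code{\link{temporal_network}}.
#' @export
read_temporal <- function(path, format = c("mtx-dir", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx-dir") read_temporal_mtx(path) else read_temporal_tsv(path)
}

read_temporal_mtx <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.mtx$", full.names = TRUE))
  if (!length(files)) stop("no .mtx files found in ", dir)
  snaps <- lapply(files, function(f) {
    M <- as.matrix(Matrix::readMM(f))
    M <- (M + t(M)) / 2  # symmetric-coordinate files store one triangle
    if (max(abs(M - t(M))) > 0) M <- (M + t(M)) / 2
    nf <- sub("\\.mtx$", ".nodes", f)
    ids <- if (file.exists(nf)) readLines(nf) else NULL
    weighted_network(unname(M), ids)
  })
  temporal_network(snaps)
}

read_temporal_tsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", "character",
                                         "numeric"))
  names(df) <- c("t", "i", "j", "w")
  times <- sort(unique(df$t))
  if (!identical(times, seq_len(max(times))))
    warning("missing time indices: ",
            paste(setdiff(seq_len(max(times)), times), collapse = ", "))
  snaps <- lapply(times, function(tt) {
    sub <- df[df$t == tt, , drop = FALSE]
    ids <- sort(unique(c(sub$i, sub$j)))
    n <- length(ids)
    if (n < 2L) stop(sprintf("time %d: fewer than 2 nodes", tt))
    M <- matrix(0, n, n, dimnames = list(ids, ids))
    seen <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(sub))) {
      a <- sub$i[r]; b <- sub$j[r]; w <- sub$w[r]
      key <- paste(sort(c(a, b)), collapse = "\r")
      prev <- get0(key, envir = seen)
      if (!is.null(prev) && prev != w)
        stop(sprintf("conflicting duplicate edge %s-%s at t=%d (line %d)",
                     a, b, tt, r + 1L))
      assign(key, w, envir = seen)
      M[a, b] <- w; M[b, a] <- w
    }
    weighted_network(unname(M), ids)
  })
  temporal_network(snaps)
}

#' Write a temporal network to disk
#'
#' @param net A \code{\link{temporal_network}}.
#' @param dir Output directory (mtx-dir format) or file path (tsv).
#' @param format \code{"mtx-dir"} or \code{"tsv"}.
#' @return The output path, invisibly.
#' @export
write_temporal <- function(net, dir, format = c("mtx-dir", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx-dir") {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (t in seq_along(net$snapshots)) {
      s <- net$snapshots[[t]]
      f <- file.path(dir, sprintf("A_%04d.mtx", t))
      Matrix::writeMM(methods::as(Matrix::Matrix(s$matrix, sparse = TRUE),
                                  "generalMatrix"), f)
      writeLines(s$node_ids, sub("\\.mtx$", ".nodes", f))
    }
  } else {
    rows <- list()
    for (t in seq_along(net$snapshots)) {
      s <- net$snapshots[[t]]
      ut <- which(upper.tri(s$matrix, diag = TRUE) & s$matrix != 0,
                  arr.ind = TRUE)
      if (nrow(ut))
        rows[[t]] <- data.frame(t = t, i = s$node_ids[ut[, 1L]],
                                j = s$node_ids[ut[, 2L]],
                                w = s$matrix[ut])
    }
    utils::write.table(do.call(rbind, rows), dir, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write per-snapshot decompositions and a JSON run log
#'
#' Emits \code{L_<t>.mtx}, \code{S_<t>.mtx}, \code{E_<t>.mtx} per time index
#' and \code{runlog.json} with per-snapshot \code{t}, \code{iterations},
#' \code{converged}, \code{residual} and \code{rank}.
#'
#' @param decs List of \code{decomposition} objects.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_decompositions <- function(decs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log <- vector("list", length(decs))
  for (t in seq_along(decs)) {
    d <- decs[[t]]
    for (nm in c("L", "S", "E")) {
      Matrix::writeMM(methods::as(Matrix::Matrix(d[[nm]], sparse = TRUE),
                                  "generalMatrix"),
                      file.path(dir, sprintf("%s_%04d.mtx", nm, t)))
    }
    log[[t]] <- list(t = t, iterations = d$iterations,
                     converged = d$converged, residual = d$residual,
                     rank = length(d$singular_values))
  }
  jsonlite::write_json(log, file.path(dir, "runlog.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
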