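# ROI time-series container, nuisance regression, and the wavelet
# connectivity matrix.

#' Construct an ROI time-series matrix
#'
#' The pipeline's entry point: one row per node (ROI), one column per
#' frame.
#'
#' @param values numeric matrix, nodes x frames, no missing values.
#' @param nodes character node ids (unique; default rownames).
#' @param tr repetition time in seconds.
#' @param subject_id optional subject identifier.
#' @return an object of class `fc_timeseries`.
#' @export
roi_timeseries <- function(values, nodes = NULL, tr, subject_id = NULL) {
  values <- as.matrix(values)
  if (anyNA(values) || !is.numeric(values))
    stopf("time-series values must be numeric with no missing entries")
  stopifnot(tr > 0)
  nodes <- nodes %||% rownames(values) %||%
    paste0("ROI", sprintf("%02d", seq_len(nrow(values))))
  if (anyDuplicated(nodes)) stopf("node ids must be unique")
  if (length(nodes) != nrow(values))
    stopf("node ids (%d) do not match rows (%d)", length(nodes), nrow(values))
  rownames(values) <- nodes
  structure(list(values = values, nodes = nodes, tr = tr,
                 n_frames = ncol(values), subject_id = subject_id),
            class = "fc_timeseries")
}

#' @export
print.fc_timeseries <- function(x, ...) {
  cat(sprintf("<fc_timeseries>%s %d nodes x %d frames, TR = %g s\n",
              if (is.null(x$subject_id)) "" else paste0(" ", x$subject_id),
              length(x$nodes), x$n_frames, x$tr))
  invisible(x)
}

#' Regress nuisance confounds out of ROI time-series
#'
#' Per-node least-squares residualization against a per-frame confound
#' matrix (e.g. the six realignment parameters plus white-matter, CSF and
#' global signals).  An intercept is always included, so the residuals are
#' mean-centered and orthogonal to every confound column.
#'
#' @param ts an `fc_timeseries`.
#' @param confounds numeric matrix, frames x regressors.
#' @return an `fc_timeseries` of residuals.
#' @export
regress_confounds <- function(ts, confounds) {
  stopifnot(inherits(ts, "fc_timeseries"))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != ts$n_frames)
    stopf("confounds have %d rows but the series has %d frames",
          nrow(confounds), ts$n_frames)
  if (ncol(confounds) > 0 && is.null(colnames(confounds)))
    colnames(confounds) <- paste0("C", seq_len(ncol(confounds)))
  x <- cbind(`(Intercept)` = 1, confounds)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stopf("confound matrix is rank deficient; collinear columns: %s",
          paste(dropped, collapse = ", "))
  }
  resid <- t(ts$values) - x %*% qr.coef(qx, t(ts$values))
  roi_timeseries(t(resid), ts$nodes, ts$tr, ts$subject_id)
}

#' Build the wavelet connectivity matrix
#'
#' For each node, the MODWT detail coefficient series of the requested
#' scales are averaged pointwise (they are same-length and shift-aligned);
#' the connectivity between two nodes is the absolute Pearson correlation
#' of their averaged coefficient series.
#'
#' @param ts an `fc_timeseries` long enough for the largest scale
#'   (frames >= 2^(max scale + 1)).
#' @param scales wavelet scales to average (default 2:4, i.e. the
#'   0.015625--0.125 Hz band at TR = 2 s).
#' @inheritParams modwt_details
#' @return an object of class `fc_connectivity`: list with `matrix`
#'   (symmetric, entries in \[0,1\], diagonal NA), `nodes`, `scales`,
#'   `undefined` (two-column matrix of pairs with zero-variance averaged
#'   series, if any).
#' @export
build_connectivity <- function(ts, scales = 2:4, filter = "la8",
                               boundary = "periodic") {
  stopifnot(inherits(ts, "fc_timeseries"))
  d <- modwt_details(t(ts$values), scales = scales, filter = filter,
                     boundary = boundary)
  avg <- Reduce(`+`, d) / length(d)  # frames x nodes
  sds <- apply(avg, 2, stats::sd)
  undefined <- NULL
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    undefined <- cbind(rep(bad, each = length(ts$nodes)),
                       rep(seq_along(ts$nodes), length(bad)))
    undefined <- undefined[undefined[, 1] != undefined[, 2], , drop = FALSE]
    warning(sprintf("zero-variance averaged coefficients for node(s): %s",
                    paste(ts$nodes[bad], collapse = ", ")))
  }
  m <- abs(suppressWarnings(stats::cor(avg)))
  diag(m) <- NA_real_
  dimnames(m) <- list(ts$nodes, ts$nodes)
  structure(list(matrix = m, nodes = ts$nodes, scales = sort(unique(scales)),
                 undefined = undefined), class = "fc_connectivity")
}

#' @export
print.fc_connectivity <- function(x, ...) {
  n <- length(x$nodes)
  cat(sprintf("<fc_connectivity> %d nodes, %d pairs; scales %s; mean |r| = %.3f\n",
              n, n * (n - 1) / 2, paste(x$scales, collapse = ","),
              mean(upper_values(x$matrix), na.rm = TRUE)))
  invisible(x)
}

#' Number of distinct node pairs of a connectivity matrix
#' @param conn an `fc_connectivity` or square matrix.
#' @return integer N(N-1)/2.
#' @export
n_pairs <- function(conn) {
  n <- nrow(unclass_conn(conn))
  as.integer(n * (n - 1) / 2)
}

#' Read / write ROI time-series TSV
#'
#' Tab-separated, one row per node with node ids in the first column and
#' one column per frame.
#'
#' @param path file path.
#' @param tr repetition time in seconds.
#' @param subject_id optional subject identifier.
#' @return an `fc_timeseries`.
#' @export
read_timeseries_tsv <- function(path, tr, subject_id = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  if (ncol(df) < 2) stopf("%s: expected node id column plus frames", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stopf("%s: duplicate node ids: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(apply(df[, -1, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stopf("%s: non-numeric values in data line(s) %s", path,
          paste(bad + 1, collapse = ", "))
  }
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1, anyNA))
    stopf("%s: missing values in data line(s) %s", path,
          paste(bad + 1, collapse = ", "))
  }
  dimnames(vals) <- NULL
  roi_timeseries(vals, ids, tr,
                 subject_id %||% sub("\\.tsv$", "", basename(path)))
}

#' @rdname read_timeseries_tsv
#' @param ts an `fc_timeseries` to write.
#' @export
write_timeseries_tsv <- function(ts, path) {
  df <- data.frame(node = ts$nodes, ts$values, check.names = FALSE)
  colnames(df) <- c("node", paste0("f", seq_len(ts$n_frames)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a connectivity matrix as TSV with node-id headers
#' @param conn an `fc_connectivity`.
#' @param path output path.
#' @export
write_connectivity_tsv <- function(conn, path) {
  m <- unclass_conn(conn)
  df <- data.frame(node = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
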