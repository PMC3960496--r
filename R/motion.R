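# Frame-wise head-motion quality control.
#
# Works on six-parameter rigid-body realignment traces in the MCFLIRT
# ".par" column order: three rotations in radians, then three translations
# in mm.  Rotations are converted to displacements as arc length on a
# 50 mm sphere (the Power et al. convention).

#' Construct a realignment trace
#'
#' @param params numeric matrix with one row per frame and six columns:
#'   rotations x, y, z (radians) then translations x, y, z (mm).
#' @param subject_id optional subject identifier.
#' @return an object of class `fc_motion_trace`.
#' @export
motion_trace <- function(params, subject_id = NULL) {
  params <- as.matrix(params)
  if (ncol(params) != 6) stopf("realignment trace needs 6 columns, got %d",
                               ncol(params))
  if (anyNA(params) || !is.numeric(params))
    stopf("realignment trace must be numeric with no missing values")
  colnames(params) <- c("rot_x", "rot_y", "rot_z",
                        "trans_x", "trans_y", "trans_z")
  structure(list(params = params, n_frames = nrow(params),
                 subject_id = subject_id), class = "fc_motion_trace")
}

#' Read a six-column realignment parameter file
#'
#' Whitespace-delimited, one row per frame, rotations (radians) before
#' translations (mm).
#'
#' @param path file path.
#' @param subject_id optional subject identifier (defaults to file name).
#' @return an `fc_motion_trace`.
#' @export
read_motion_par <- function(path, subject_id = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  motion_trace(m, subject_id = subject_id %||%
                 sub("\\.par$", "", basename(path)))
}

#' Write a realignment trace in the six-column dialect
#' @param trace an `fc_motion_trace`.
#' @param path output path.
#' @export
write_motion_par <- function(trace, path) {
  utils::write.table(format(trace$params, digits = 8, scientific = FALSE),
                     path, sep = "  ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

trace_params <- function(trace) {
  if (inherits(trace, "fc_motion_trace")) trace$params else
    motion_trace(trace)$params
}

#' Frame-wise displacement (FD)
#'
#' Per frame, the sum of the absolute differentials of the six realignment
#' parameters, with rotational differentials converted to mm as arc length
#' on a sphere of radius `rotation_radius`:
#' \eqn{FD_t = \sum |\Delta trans| + r \sum |\Delta rot|}.
#'
#' @param trace an `fc_motion_trace` with at least 2 frames.
#' @param rotation_radius sphere radius in mm (default 50).
#' @return numeric vector of length `frames - 1`.
#' @export
framewise_displacement <- function(trace, rotation_radius = 50) {
  p <- trace_params(trace)
  if (nrow(p) < 2) stopf("framewise displacement needs at least 2 frames")
  d <- abs(diff(p))
  rowSums(d[, 4:6, drop = FALSE]) +
    rotation_radius * rowSums(d[, 1:3, drop = FALSE])
}

#' Mean Motion
#'
#' Mean frame-to-frame translational displacement of the head.  The
#' default follows the Van Dijk convention: the mean over frames of the
#' Euclidean norm of the translation differential.  `method = "per_axis"`
#' instead averages the absolute differentials of the three axes
#' separately and then together (the literal per-axis reading).
#'
#' @param trace an `fc_motion_trace` with at least 2 frames.
#' @param method `"norm"` (default) or `"per_axis"`.
#' @return mean displacement in mm.
#' @export
mean_motion <- function(trace, method = c("norm", "per_axis")) {
  method <- match.arg(method)
  p <- trace_params(trace)
  if (nrow(p) < 2) stopf("mean motion needs at least 2 frames")
  d <- diff(p[, 4:6, drop = FALSE])
  if (method == "norm") mean(sqrt(rowSums(d^2))) else mean(abs(d))
}

#' Motion summary for one subject
#'
#' Bundles the frame-wise metrics: the FD series, the per-parameter
#' absolute differentials (Diff), and Mean Motion.
#'
#' @inheritParams framewise_displacement
#' @param mean_motion_method passed to [mean_motion()].
#' @return an object of class `fc_motion_summary` with `fd_series`,
#'   `diff_series` (matrix, (frames-1) x 6), `mean_motion`,
#'   `max_param_mm` (largest converted parameter magnitude), and
#'   `subject_id`.
#' @export
motion_summary <- function(trace, rotation_radius = 50,
                           mean_motion_method = "norm") {
  p <- trace_params(trace)
  conv <- cbind(p[, 1:3, drop = FALSE] * rotation_radius,
                p[, 4:6, drop = FALSE])
  structure(list(
    fd_series = framewise_displacement(trace, rotation_radius),
    diff_series = abs(diff(p)),
    mean_motion = mean_motion(trace, mean_motion_method),
    max_param_mm = max(abs(conv)),
    rotation_radius = rotation_radius,
    subject_id = if (inherits(trace, "fc_motion_trace")) trace$subject_id),
    class = "fc_motion_summary")
}

#' @export
print.fc_motion_summary <- function(x, ...) {
  cat(sprintf("<fc_motion_summary>%s mean FD %.3f mm, Mean Motion %.3f mm, max |param| %.3f mm\n",
              if (is.null(x$subject_id)) "" else paste0(" ", x$subject_id),
              mean(x$fd_series), x$mean_motion, x$max_param_mm))
  invisible(x)
}

#' Apply the subject-exclusion rules
#'
#' A subject is excluded when any of the six realignment parameters
#' (rotations converted to mm on the 50 mm sphere) deviates by more than
#' `param_limit` mm, or when Mean Motion exceeds `mean_motion_limit` mm.
#'
#' @param summary an `fc_motion_summary` computed from `trace`.
#' @param trace the corresponding `fc_motion_trace`.
#' @param param_limit per-parameter deviation limit in mm (default 1.0).
#' @param mean_motion_limit Mean Motion limit in mm (default 0.25).
#' @return list with `excluded` (logical) and `reasons` (character vector,
#'   subset of `"parameter_deviation"`, `"mean_motion"`).
#' @export
apply_exclusion <- function(summary, trace, param_limit = 1.0,
                            mean_motion_limit = 0.25) {
  stopifnot(inherits(summary, "fc_motion_summary"))
  reasons <- character(0)
  if (summary$max_param_mm > param_limit)
    reasons <- c(reasons, "parameter_deviation")
  if (summary$mean_motion > mean_motion_limit)
    reasons <- c(reasons, "mean_motion")
  list(excluded = length(reasons) > 0, reasons = reasons)
}

#' Motion--connectivity association check
#'
#' Tests whether subject-level connectivity tracks subject-level head
#' motion, with a linear (Pearson) and a rank (Spearman) correlation.
#'
#' @param mean_motions per-subject Mean Motion (mm).
#' @param connectivity_values per-subject connectivity values (e.g. one
#'   edge's |r| per subject), same length, n >= 3.
#' @return data.frame with one row per method: estimate, p value, and a
#'   `defined` flag (FALSE when a vector has zero variance).
#' @export
motion_connectivity_check <- function(mean_motions, connectivity_values) {
  x <- as.numeric(mean_motions)
  y <- as.numeric(connectivity_values)
  if (length(x) != length(y)) stopf("input vectors must have equal length")
  if (length(x) < 3) stopf("need at least 3 subjects")
  run <- function(method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(method = method, estimate = NA_real_, p = NA_real_,
                        defined = FALSE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    data.frame(method = method, estimate = unname(ct$estimate),
               p = ct$p.value, defined = TRUE)
  }
  rbind(run("pearson"), run("spearman"))
}
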