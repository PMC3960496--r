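# Maximum-overlap discrete wavelet transform (MODWT) for ROI time-series.
#
# The MODWT is the undecimated form of the DWT: every scale keeps one
# coefficient per time point, so coefficient series from different scales
# stay aligned and can be averaged pointwise.  Scale k of a series sampled
# every TR seconds carries the frequency octave [2^(-k-1)/TR, 2^(-k)/TR].

# Daubechies least-asymmetric length-8 ("LA(8)" / sym4) scaling filter,
# standard in the fMRI wavelet-connectivity literature.
la8_scaling <- function() {
  c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
    0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
    -0.01260396726203783, 0.03222310060404270)
}

# Haar, kept as a minimal alternative filter
haar_scaling <- function() c(1, 1) / sqrt(2)

wavelet_filter_pair <- function(filter = c("la8", "haar")) {
  filter <- match.arg(filter)
  g <- switch(filter, la8 = la8_scaling(), haar = haar_scaling())
  L <- length(g)
  # quadrature mirror: h_l = (-1)^l g_{L-1-l}
  h <- (-1)^(0:(L - 1)) * rev(g)
  list(g = g, h = h, L = L)
}

#' Frequency passband of a wavelet scale
#'
#' Returns the frequency octave carried by the kth wavelet scale of a series
#' sampled every `tr` seconds: \eqn{[2^{-k-1}/TR,\; 2^{-k}/TR]} Hz.  At
#' TR = 2 s the scales 2, 3 and 4 cover 0.0625--0.125, 0.03125--0.0625 and
#' 0.015625--0.03125 Hz, whose union 0.0156--0.125 Hz is the band usually
#' analyzed in block-design task fMRI.
#'
#' @param k wavelet scale index (k >= 1).
#' @param tr repetition time in seconds.
#' @return numeric vector `c(f_low, f_high)` in Hz.
#' @examples
#' scale_passband(3, tr = 2)  # 0.03125 0.06250
#' @export
scale_passband <- function(k, tr) {
  stopifnot(k >= 1, tr > 0)
  c(f_low = 2^(-k - 1) / tr, f_high = 2^(-k) / tr)
}

# one MODWT pyramid step on the columns of a matrix (frames x series),
# circular (periodic) boundary: out[t] = sum_l f[l+1] * x[(t - 2^(j-1) l) mod n]
modwt_step <- function(x, f, level) {
  n <- nrow(x)
  s <- 2^(level - 1)
  out <- matrix(0, n, ncol(x))
  t0 <- 0:(n - 1)
  for (l in seq_along(f)) {
    idx <- ((t0 - s * (l - 1)) %% n) + 1
    out <- out + f[l] * x[idx, , drop = FALSE]
  }
  out
}

#' MODWT detail coefficients of one or more series
#'
#' Computes undecimated (same-length, shift-aligned) wavelet detail
#' coefficient series at the requested scales via the MODWT pyramid
#' algorithm.  Periodic boundary handling is the default so that all
#' coefficient series have exactly the input length and the transform is
#' equivariant under circular shifts; a reflection variant is available.
#'
#' @param x numeric vector, or matrix with one series per column.
#' @param scales integer scale indices (default 2:4, the three octaves
#'   below 0.125 Hz at TR = 2 s).
#' @param filter wavelet filter family, `"la8"` (default) or `"haar"`.
#' @param boundary `"periodic"` (default) or `"reflection"`.
#' @return a named list with one element per scale; each element has the
#'   same shape as `x`.
#' @export
modwt_details <- function(x, scales = 2:4, filter = "la8",
                          boundary = c("periodic", "reflection")) {
  boundary <- match.arg(boundary)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  if (anyNA(x)) stopf("input series contain missing values")
  scales <- sort(unique(as.integer(scales)))
  stopifnot(all(scales >= 1))
  jmax <- max(scales)
  n <- nrow(x)
  need <- 2^(jmax + 1)
  if (n < need)
    stopf("series of length %d too short for wavelet scale %d (need >= %d frames)",
          n, jmax, need)
  fp <- wavelet_filter_pair(filter)
  # MODWT filters are the unit-scale filters divided by sqrt(2)
  g <- fp$g / sqrt(2)
  h <- fp$h / sqrt(2)

  if (boundary == "reflection") {
    x <- rbind(x, x[n:1, , drop = FALSE])  # even reflection, then periodic
  }
  v <- x
  details <- vector("list", length(scales))
  names(details) <- paste0("scale", scales)
  for (j in seq_len(jmax)) {
    if (j %in% scales) {
      w <- modwt_step(v, h, j)
      k <- match(j, scales)
      details[[k]] <- if (boundary == "reflection") w[seq_len(n), , drop = FALSE] else w
    }
    v <- modwt_step(v, g, j)
  }
  if (vec) details <- lapply(details, drop)
  details
}

#' Band-limited wavelet coefficients of a single series
#'
#' Convenience wrapper around [modwt_details()] for one node's signal:
#' returns the per-scale detail series plus the passband each scale carries
#' at the given TR.
#'
#' @param series numeric vector.
#' @param scales integer scale indices (default 2:4).
#' @param tr repetition time in seconds.
#' @inheritParams modwt_details
#' @return list with `coefficients` (matrix, frames x scales) and
#'   `passbands` (matrix, scales x 2, Hz).
#' @export
wavelet_band_coefficients <- function(series, scales = 2:4, tr,
                                      filter = "la8", boundary = "periodic") {
  stopifnot(is.numeric(series), tr > 0)
  d <- modwt_details(series, scales = scales, filter = filter,
                     boundary = boundary)
  co <- do.call(cbind, d)
  colnames(co) <- names(d)
  pb <- t(vapply(sort(unique(as.integer(scales))), scale_passband,
                 numeric(2), tr = tr))
  rownames(pb) <- colnames(co)
  list(coefficients = co, passbands = pb)
}
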