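#' Interpolate blink and artifact gaps in a pupil series
#'
#' Gaps are runs of the missing sentinel (zero) or non-finite values. Each
#' run is dilated by a margin on both sides -- video-based trackers distort
#' pupil estimates around lid closure -- and replaced by linear
#' interpolation (edge gaps are extended from the nearest valid value).
#'
#' @param values Raw pupil vector.
#' @param rate_hz Sampling rate, Hz.
#' @param margin_s Dilation margin per side, seconds (default 0.05).
#' @param zero_is_missing Treat exact zeros as the missing sentinel.
#' @return List with `values` (gap-free) and `blink` (0/1 vector marking
#'   every replaced sample, margins included).
#' @export
preprocess_pupil <- function(values, rate_hz, margin_s = 0.05,
                             zero_is_missing = TRUE) {
  v <- as.numeric(values)
  n <- length(v)
  miss <- !is.finite(v)
  if (zero_is_missing) miss <- miss | (!is.na(v) & v == 0)
  if (all(miss)) stop("series is entirely missing", call. = FALSE)
  m <- max(0L, round(margin_s * rate_hz))
  if (m > 0L && any(miss)) {
    idx <- which(miss)
    grow <- unique(unlist(lapply(idx, function(i)
      max(1L, i - m):min(n, i + m))))
    miss[grow] <- TRUE
  }
  v[miss] <- NA_real_
  v <- zoo::na.approx(v, na.rm = FALSE, rule = 2)
  list(values = as.numeric(v), blink = as.integer(miss))
}

#' Savitzky-Golay smoothing for ground-truth phase labelling
#'
#' Window length is the odd sample count nearest to 0.1 s at the given
#' rate; polynomial order 3. High-frequency noise is removed so that local
#' extrema and gradient signs reflect the underlying fluctuation. When the
#' window is too short for the polynomial order (`window < order + 2`) the
#' input is returned unsmoothed with a warning.
#'
#' @param values Gap-free numeric vector.
#' @param rate_hz Sampling rate, Hz.
#' @param window_s Smoothing window, seconds.
#' @param order Polynomial order.
#' @return Smoothed numeric vector.
#' @export
smooth_for_truth <- function(values, rate_hz, window_s = 0.1, order = 3) {
  w <- round(window_s * rate_hz)
  if (w %% 2 == 0) w <- w + 1L
  if (w < order + 2) {
    warning("smoothing window shorter than order + 2; returning input")
    return(values)
  }
  if (length(values) < w) {
    warning("series shorter than the smoothing window; returning input")
    return(values)
  }
  as.numeric(signal::sgolayfilt(values, p = order, n = w))
}

#' Topographic prominence of local maxima
#'
#' For each peak, scan outwards until a strictly higher sample (or the
#' series edge) on each side; the base on that side is the minimum over the
#' scanned interval. Prominence is peak height minus the higher of the two
#' bases.
#'
#' @param y Numeric vector without `NA`.
#' @param peaks Integer indices of local maxima (see [local_maxima()]).
#' @return Numeric vector of prominences, aligned with `peaks`.
#' @export
peak_prominences <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(p) {
    h <- y[p]
    i <- p
    lmin <- h
    while (i > 1L) {
      i <- i - 1L
      if (y[i] > h) break
      if (y[i] < lmin) lmin <- y[i]
    }
    i <- p
    rmin <- h
    while (i < n) {
      i <- i + 1L
      if (y[i] > h) break
      if (y[i] < rmin) rmin <- y[i]
    }
    h - max(lmin, rmin)
  }, 0)
}

#' Ground-truth peak and trough indices from a smoothed series
#'
#' Local maxima are ranked by topographic prominence and the most prominent
#' `keep_fraction` retained (prominence at or above the
#' `1 - keep_fraction` quantile; ties kept). Troughs are found identically
#' on the negated series. Binary index vectors are set to 1 within
#' `half_window_s` before and after each kept event -- a detection landing
#' anywhere in that window counts as on-phase.
#'
#' @param smoothed Smoothed, gap-free pupil vector.
#' @param rate_hz Sampling rate, Hz.
#' @param keep_fraction Fraction of extrema to keep by prominence
#'   (default 0.75; some recordings warrant 0.90).
#' @param half_window_s Half-width of the index window, seconds.
#' @return List: `peak_index`, `trough_index` (0/1 vectors),
#'   `peak_samples`, `trough_samples` (kept extremum indices).
#' @export
true_extrema_index <- function(smoothed, rate_hz, keep_fraction = 0.75,
                               half_window_s = 0.25) {
  n <- length(smoothed)
  w <- round(half_window_s * rate_hz)
  mark <- function(centers) {
    v <- integer(n)
    for (c0 in centers) v[max(1L, c0 - w):min(n, c0 + w)] <- 1L
    v
  }
  keep_by_prominence <- function(y) {
    pk <- local_maxima(y)
    if (!length(pk)) return(integer())
    pr <- peak_prominences(y, pk)
    thr <- stats::quantile(pr, 1 - keep_fraction, type = 7)
    pk[pr >= thr]
  }
  pks <- keep_by_prominence(smoothed)
  trs <- keep_by_prominence(-smoothed)
  list(peak_index = mark(pks), trough_index = mark(trs),
       peak_samples = pks, trough_samples = trs)
}

#' Ground-truth dilation and constriction indices from the gradient
#'
#' Central-difference slope at every sample (one-sided at the edges):
#' positive slope marks dilation, negative marks constriction; zero-slope
#' samples belong to neither index.
#'
#' @param smoothed Smoothed, gap-free pupil vector (length >= 2).
#' @return List: `dilation_index`, `constriction_index` (0/1 vectors),
#'   `slope`.
#' @export
true_gradient_index <- function(smoothed) {
  n <- length(smoothed)
  stopifnot(n >= 2L)
  g <- numeric(n)
  if (n > 2L)
    g[2:(n - 1)] <- (smoothed[3:n] - smoothed[1:(n - 2)]) / 2
  g[1] <- smoothed[2] - smoothed[1]
  g[n] <- smoothed[n] - smoothed[n - 1]
  list(dilation_index = as.integer(g > 0),
       constriction_index = as.integer(g < 0),
       slope = g)
}

#' Velocity-threshold saccade detection from gaze position
#'
#' Smoothed velocity by central differences over +/-2 samples; per-axis
#' thresholds at `lambda` times a median-based velocity SD; samples whose
#' velocity exceeds the elliptic criterion in runs of at least
#' `min_duration_samples` are marked 1. A simplified reimplementation of
#' the standard microsaccade-inclusive velocity method.
#'
#' @param gaze_x,gaze_y Gaze position vectors (same length), or `NULL`.
#' @param rate_hz Sampling rate, Hz.
#' @param lambda Threshold multiplier (default 6).
#' @param min_duration_samples Minimum run length (default 3).
#' @return 0/1 integer vector; all zeros (with a warning) when gaze is
#'   absent.
#' @export
detect_saccades <- function(gaze_x, gaze_y, rate_hz, lambda = 6,
                            min_duration_samples = 3) {
  if (is.null(gaze_x) || is.null(gaze_y)) {
    warning("gaze channels absent; returning all-zero saccade vector")
    return(integer(0))
  }
  stopifnot(length(gaze_x) == length(gaze_y))
  n <- length(gaze_x)
  out <- integer(n)
  if (n < 5L) return(out)
  vel <- function(x) {
    v <- numeric(n)
    i <- 3:(n - 2)
    v[i] <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) * rate_hz / 6
    v
  }
  vx <- vel(gaze_x)
  vy <- vel(gaze_y)
  msd <- function(v) {
    s2 <- stats::median(v^2) - stats::median(v)^2
    sqrt(max(s2, 0))
  }
  sx <- msd(vx)
  sy <- msd(vy)
  if (sx == 0 || sy == 0) return(out)
  crit <- (vx / (lambda * sx))^2 + (vy / (lambda * sy))^2 > 1
  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values & r$lengths >= min_duration_samples))
    out[starts[j]:ends[j]] <- 1L
  out
}
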