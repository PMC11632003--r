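#' Extract event-locked epochs from a recording-long vector
#'
#' Cuts a window of `half_width_s` on each side of every event time
#' (5001 samples at 1000 Hz for a 2.5 s half-width; 1001 at 0.5 s). Events
#' whose window would cross either end of the recording are skipped. Pupil
#' epochs are demeaned (epoch mean subtracted from every sample); binary
#' blink/saccade epochs are left as 0/1.
#'
#' @param values Recording-long numeric vector (cleaned pupil, or binary).
#' @param event_times Event times, seconds.
#' @param rate_hz Sampling rate, Hz.
#' @param half_width_s Half-width, seconds (2.5 human/mouse; 0.5 monkey).
#' @param t0 Time of the first sample.
#' @param demean Demean each epoch (`TRUE` for pupil, `FALSE` for binary).
#' @return An `epoch_set`: list with `data` (events x samples matrix),
#'   `times_s` (relative sample times), `center_index`, `event_times`
#'   (the surviving events), `half_width_s`, `rate_hz`.
#' @export
extract_epochs <- function(values, event_times, rate_hz,
                           half_width_s = 2.5, t0 = 0, demean = TRUE) {
  n <- length(values)
  w <- round(half_width_s * rate_hz)
  centers <- round((event_times - t0) * rate_hz) + 1L
  ok <- centers - w >= 1L & centers + w <= n
  centers <- centers[ok]
  m <- matrix(NA_real_, length(centers), 2L * w + 1L)
  for (i in seq_along(centers))
    m[i, ] <- values[(centers[i] - w):(centers[i] + w)]
  if (demean && nrow(m)) m <- m - rowMeans(m)
  out <- list(data = m,
              times_s = (seq_len(2L * w + 1L) - w - 1L) / rate_hz,
              center_index = w + 1L,
              event_times = event_times[ok],
              half_width_s = half_width_s,
              rate_hz = rate_hz)
  class(out) <- "epoch_set"
  out
}

#' Remove the best-fit line from every epoch
#'
#' Applied to demeaned pupil epochs to correct slow within-epoch drift
#' (used for short monkey trial epochs). Idempotent up to numerical
#' tolerance; an exactly linear epoch maps to zeros.
#'
#' @param epochs An `epoch_set`.
#' @return The detrended `epoch_set`.
#' @export
detrend_epochs <- function(epochs) {
  m <- epochs$data
  if (!nrow(m)) return(epochs)
  k <- ncol(m)
  x <- seq_len(k) - (k + 1) / 2          # centered abscissa
  sxx <- sum(x * x)
  slope <- as.numeric(m %*% x) / sxx
  inter <- rowMeans(m)
  epochs$data <- m - outer(inter, rep(1, k)) - outer(slope, x)
  epochs
}

#' Group-level event-locked time courses
#'
#' Each subject contributes the mean across its epochs; the group curve is
#' the mean across subjects with the SEM. In `zscore_mean` mode each
#' subject-mean curve is standardized over its own time samples before
#' averaging, giving every subject equal weight regardless of pupil-size
#' units.
#'
#' @param epoch_sets List of per-subject `epoch_set` objects (same epoch
#'   geometry).
#' @param mode `"mean"` or `"zscore_mean"`.
#' @return List: `mean`, `sem` (`NA` with a single subject), `times_s`,
#'   `subject_curves` (subjects x samples matrix).
#' @export
group_time_courses <- function(epoch_sets, mode = c("mean",
                                                    "zscore_mean")) {
  mode <- match.arg(mode)
  curves <- t(vapply(epoch_sets, function(e) colMeans(e$data),
                     numeric(ncol(epoch_sets[[1]]$data))))
  if (mode == "zscore_mean")
    curves <- t(apply(curves, 1, function(c0)
      (c0 - mean(c0)) / stats::sd(c0)))
  ns <- nrow(curves)
  list(mean = colMeans(curves),
       sem = if (ns > 1) apply(curves, 2, stats::sd) / sqrt(ns)
             else rep(NA_real_, ncol(curves)),
       times_s = epoch_sets[[1]]$times_s,
       subject_curves = curves)
}

#' Occurrence-fraction time courses from binary epochs
#'
#' The per-time mean across binary epochs is the fraction of events with
#' (e.g.) a blink at that latency. Saccade curves are additionally smoothed
#' with a centered moving average (edge windows shrink symmetrically).
#'
#' @param epochs An `epoch_set` of 0/1 epochs.
#' @param smooth_window_s Moving-average window in seconds, or `NULL` for
#'   none.
#' @return List: `fraction`, `times_s`.
#' @export
fraction_time_courses <- function(epochs, smooth_window_s = NULL) {
  f <- colMeans(epochs$data)
  if (!is.null(smooth_window_s)) {
    k <- round(smooth_window_s * epochs$rate_hz)
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1L) f <- moving_average(f, k)
  }
  list(fraction = f, times_s = epochs$times_s)
}

# centered moving average with symmetrically shrinking edge windows
moving_average <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + r + 1L] - cs[i - r]) / (2L * r + 1L)
  }
  out
}

#' Drop events with eye movements just before the event time
#'
#' Keeps only events with neither a blink nor a saccade sample set in the
#' `pre_window_s` seconds before (and excluding) the event time, isolating
#' detections not driven by ocular artifacts.
#'
#' @param event_times Event times, seconds.
#' @param blink,saccade 0/1 recording-long vectors (either may be `NULL`).
#' @param rate_hz Sampling rate, Hz.
#' @param pre_window_s Look-back window, seconds.
#' @param t0 Time of the first sample.
#' @return Logical keep vector aligned with `event_times`.
#' @export
exclude_eye_movement_epochs <- function(event_times, blink = NULL,
                                        saccade = NULL, rate_hz,
                                        pre_window_s = 0.5, t0 = 0) {
  w <- round(pre_window_s * rate_hz)
  n <- max(length(blink), length(saccade))
  vapply(event_times, function(tt) {
    c0 <- round((tt - t0) * rate_hz) + 1L
    lo <- max(1L, c0 - w)
    hi <- c0 - 1L
    if (hi < lo) return(TRUE)
    bad <- FALSE
    if (!is.null(blink)) bad <- any(blink[lo:min(hi, length(blink))] == 1L)
    if (!bad && !is.null(saccade))
      bad <- any(saccade[lo:min(hi, length(saccade))] == 1L)
    !bad
  }, TRUE)
}
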