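#' Parameters for the synthetic pupillary-unrest generator
#'
#' Describes a simulated constant-luminance pupil recording: a sum of
#' sinusoidal components dominated by a ~0.5 Hz fluctuation (with smaller
#' components up to the ~3.5 Hz evoked range), a Gaussian random-walk
#' baseline drift, white measurement noise, and blink artifacts encoded as
#' runs of the zero sentinel -- the missing-data dialect of human
#' video-based eye trackers.
#'
#' Default amplitudes are in arbitrary device units on an eye-tracker
#' pupil-area-like scale (baseline ~3000 a.u., dominant fluctuation
#' ~120 a.u., with a steep spectral fall-off toward the evoked range).
#' The generated trace represents the device's *recorded* (file) output,
#' which research-grade trackers filter heavily: sample-to-sample jitter
#' is small (`noise_sd` 0.2 a.u.) and roughness at the sample scale comes
#' mainly from the random-walk drift. The noisier real-time link stream is
#' emulated separately at replay time (see [replay()]).
#'
#' @param duration_s Recording length, seconds.
#' @param rate_hz Sampling rate, Hz.
#' @param components Data frame with columns `freq_hz`, `amplitude`,
#'   `phase` (radians). `NA` phases are randomized per recording.
#' @param drift_sd Random-walk innovation scale, a.u. per sqrt(second).
#' @param noise_sd White-noise standard deviation, a.u.
#' @param blink_rate Blink onsets per second (Poisson); 0 disables blinks.
#' @param blink_duration_range Two numbers, uniform blink duration
#'   bounds in seconds.
#' @param baseline Constant positive offset, a.u.
#' @param seed Optional integer seed.
#' @return An object of class `unrest_params` (named list).
#' @export
unrest_params <- function(duration_s = 600,
                          rate_hz = 60,
                          components = data.frame(
                            freq_hz = c(0.5, 1.1, 2.2, 3.4),
                            amplitude = c(120, 25, 8, 3),
                            phase = NA_real_),
                          drift_sd = 5,
                          noise_sd = 0.2,
                          blink_rate = 0.1,
                          blink_duration_range = c(0.1, 0.3),
                          baseline = 3000,
                          seed = NULL) {
  stopifnot(duration_s > 0, rate_hz > 0,
            all(components$freq_hz > 0),
            all(components$freq_hz < rate_hz / 2),
            length(blink_duration_range) == 2L,
            blink_duration_range[1] <= blink_duration_range[2])
  p <- list(duration_s = duration_s, rate_hz = rate_hz,
            components = components, drift_sd = drift_sd,
            noise_sd = noise_sd, blink_rate = blink_rate,
            blink_duration_range = blink_duration_range,
            baseline = baseline, seed = seed)
  class(p) <- "unrest_params"
  p
}

#' Generate a synthetic pupillary-unrest recording with analytic truth
#'
#' The signal is `baseline + sum_k A_k sin(2*pi*f_k*t + phi_k) + drift +
#' noise`, sampled at `rate_hz`. Ground truth is computed from the
#' noise-free, drift-free component sum: its extrema times (root-refined
#' from the analytic derivative) and per-sample gradient sign. Blinks are
#' injected afterwards via [inject_blinks()], so the zero-sentinel path of
#' the detector is exercised end-to-end.
#'
#' @param params An [unrest_params()] object.
#' @return A list of class `pupil_recording`: `data` (data frame `time_s`,
#'   `pupil`), `dialect` (`"synthetic"`), `truth` (list with `clean`,
#'   `gradient`, `peak_times`, `trough_times`), `blink` (binary vector),
#'   `params`.
#' @export
generate_unrest <- function(params = unrest_params()) {
  stopifnot(inherits(params, "unrest_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- round(params$duration_s * params$rate_hz)
  t <- (seq_len(n) - 1) / params$rate_hz
  comp <- params$components
  phase <- comp$phase
  phase[is.na(phase)] <- stats::runif(sum(is.na(phase)), 0, 2 * pi)

  clean <- rep(0, n)
  for (k in seq_len(nrow(comp)))
    clean <- clean + comp$amplitude[k] *
      sin(2 * pi * comp$freq_hz[k] * t + phase[k])

  drift <- cumsum(stats::rnorm(n, 0, params$drift_sd /
                                 sqrt(params$rate_hz)))
  noise <- stats::rnorm(n, 0, params$noise_sd)
  pupil <- params$baseline + clean + drift + noise

  deriv <- function(x) {
    s <- 0
    for (k in seq_len(nrow(comp)))
      s <- s + comp$amplitude[k] * 2 * pi * comp$freq_hz[k] *
        cos(2 * pi * comp$freq_hz[k] * x + phase[k])
    s
  }
  g <- deriv(t)
  ext <- find_sign_change_roots(deriv, t, g)

  rec <- list(
    data = data.frame(time_s = t, pupil = pupil),
    dialect = "synthetic",
    truth = list(clean = clean, gradient = g,
                 peak_times = ext$maxima, trough_times = ext$minima),
    blink = integer(n),
    params = params)
  class(rec) <- "pupil_recording"

  if (params$blink_rate > 0) {
    bl <- inject_blinks(rec$data$pupil, params$rate_hz, params$blink_rate,
                        params$blink_duration_range)
    rec$data$pupil <- bl$values
    rec$blink <- bl$blink
  }
  rec
}

# locate roots of f along grid t (f(t) precomputed as g), classify by the
# sign of the slope before the crossing: + -> - is a maximum
find_sign_change_roots <- function(f, t, g) {
  s <- sign(g)
  idx <- which(s[-length(s)] * s[-1] < 0)
  maxima <- numeric(); minima <- numeric()
  for (i in idx) {
    r <- stats::uniroot(f, lower = t[i], upper = t[i + 1],
                        tol = 1e-10)$root
    if (s[i] > 0) maxima <- c(maxima, r) else minima <- c(minima, r)
  }
  # grid points that are exact roots with a sign change around them
  list(maxima = maxima, minima = minima)
}

#' Inject blink artifacts into a positive-valued pupil series
#'
#' Blink onsets follow a Poisson process; each blink replaces a run of
#' samples (duration uniform within `duration_range`) with the zero
#' sentinel used by the human missing-data dialect.
#'
#' @param values Positive numeric vector.
#' @param rate_hz Sampling rate, Hz.
#' @param blink_rate Blink onsets per second.
#' @param duration_range Two numbers, seconds.
#' @return List with `values` (zeros inserted) and `blink` (0/1 integer
#'   vector marking exactly the replaced samples).
#' @export
inject_blinks <- function(values, rate_hz, blink_rate,
                          duration_range = c(0.1, 0.3)) {
  n <- length(values)
  blink <- integer(n)
  if (blink_rate <= 0 || n == 0L)
    return(list(values = values, blink = blink))
  span <- n / rate_hz
  t <- 0
  repeat {
    t <- t + stats::rexp(1, blink_rate)
    if (t > span) break
    dur <- stats::runif(1, duration_range[1], duration_range[2])
    i0 <- max(1L, floor(t * rate_hz) + 1L)
    i1 <- min(n, i0 + max(1L, round(dur * rate_hz)) - 1L)
    blink[i0:i1] <- 1L
  }
  values[blink == 1L] <- 0
  list(values = values, blink = blink)
}

#' Simulate a cohort of synthetic subjects
#'
#' Per-subject seeds are derived deterministically from the master seed;
#' subjects differ in randomized component phases, amplitude jitter
#' (uniform within +/-25%), and frequency jitter (uniform within +/-10%,
#' reflecting individual variation in the dominant unrest rhythm), so
#' inter-subject signals decorrelate over the recording.
#'
#' @param n_subjects Number of recordings.
#' @param params Template [unrest_params()]; its `seed` is ignored.
#' @param seed Master integer seed.
#' @return List of `pupil_recording` objects.
#' @export
make_cohort <- function(n_subjects, params = unrest_params(), seed = 1) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    p <- params
    p$seed <- (as.integer(seed) * 1009L + i * 7919L) %% 2147483647L
    set.seed(p$seed)
    comp <- p$components
    comp$phase <- stats::runif(nrow(comp), 0, 2 * pi)
    comp$amplitude <- comp$amplitude * stats::runif(nrow(comp), 0.75, 1.25)
    comp$freq_hz <- comp$freq_hz * stats::runif(nrow(comp), 0.9, 1.1)
    p$components <- comp
    p$seed <- p$seed + 1L
    generate_unrest(p)
  })
}

#' @export
print.pupil_recording <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf("<pupil_recording> %d samples, %.1f s at %.4g Hz (%s dialect)\n",
              n, n / x$params$rate_hz, x$params$rate_hz, x$dialect))
  cat(sprintf("  blinked samples: %d (%.1f%%)\n", sum(x$blink),
              100 * mean(x$blink)))
  invisible(x)
}
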