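# duration bookkeeping uses a small tolerance so that n/rate comparisons at
# binary-inexact rates (1/60 s, ...) behave like exact arithmetic
.dur_eps <- 1e-9

#' Quadratic fit of a search window
#'
#' Demeans the window (mean of all values subtracted), fits a degree-2
#' least-squares polynomial over abscissae `0 .. n-1`, and returns the
#' fitted value at the final abscissa -- the quantity successive detector
#' iterations compare to classify the current pupil phase.
#'
#' Windows of fewer than 3 points are interpolated exactly (any quadratic
#' through <= 3 points passes through the data), so the final value is the
#' last demeaned observation.
#'
#' @param values Numeric vector, the concatenated search-window samples;
#'   must contain no `NA`/`NaN`.
#' @return A list with `final_value` and `n`.
#' @export
fit_search_window <- function(values) {
  if (anyNA(values))
    stop("search window must be NaN-free at fit time", call. = FALSE)
  n <- length(values)
  if (n < 2L) stop("search window needs >= 2 points", call. = FALSE)
  y <- values - mean(values)
  if (n <= 3L) return(list(final_value = y[n], n = n))
  x <- seq_len(n) - 1
  X <- cbind(1, x, x * x)
  beta <- stats::.lm.fit(X, y)$coefficients
  xn <- n - 1
  list(final_value = sum(beta * c(1, xn, xn * xn)), n = n)
}

#' Classify the current pupil phase from two successive fitted values
#'
#' Applies the four threshold rules in fixed precedence
#' peak -> trough -> dilation -> constriction, so at most one event is
#' emitted per fit:
#' * peak: `fv_curr < fv_prev` and `fv_curr > peak_size`
#' * trough: `fv_curr > fv_prev` and `fv_curr < trough_size`
#' * dilation: `fv_curr - fv_prev > dilation_derivative`
#' * constriction: `fv_curr - fv_prev < constriction_derivative`
#'
#' @param fv_prev,fv_curr Final fitted values of the previous and current
#'   search-window models.
#' @param thresholds Named list or vector with `peak_size`, `trough_size`,
#'   `dilation_derivative`, `constriction_derivative`.
#' @return One of `"peak"`, `"trough"`, `"dilation"`, `"constriction"`, or
#'   `NA_character_` when no rule fires (or either value is non-finite).
#' @export
classify_phase <- function(fv_prev, fv_curr, thresholds) {
  if (!is.finite(fv_prev) || !is.finite(fv_curr)) return(NA_character_)
  th <- as.list(thresholds)
  d <- fv_curr - fv_prev
  if (fv_curr < fv_prev && fv_curr > th$peak_size) return("peak")
  if (fv_curr > fv_prev && fv_curr < th$trough_size) return("trough")
  if (d > th$dilation_derivative) return("dilation")
  if (d < th$constriction_derivative) return("constriction")
  NA_character_
}

#' Strict local maxima of a numeric series
#'
#' A sample is a local maximum when strictly greater than both neighbours;
#' a plateau (run of equal values) strictly above both flanking runs is
#' reported at its first index. Endpoints are never maxima.
#'
#' @param y Numeric vector without `NA`.
#' @return Integer indices of the maxima.
#' @export
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  r <- rle(as.numeric(y))
  k <- length(r$values)
  if (k < 3L) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- 2:(k - 1L)
  hit <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  starts[j][hit]
}

#' Re-estimate detector thresholds from a filled baseline window
#'
#' If fewer than half the window samples are valid (non-`NaN`) the
#' thresholds are returned unchanged (the caller clears the window either
#' way). Otherwise the valid samples are demeaned and:
#' * `peak_size` <- `peak_percentile` of local-maximum values,
#' * `trough_size` <- `trough_percentile` of local-minimum values (minima
#'   located on the negated series; values taken from the un-negated one),
#' * derivative thresholds <- `dilation_percentile` /
#'   `constriction_percentile` of successive differences of the NaN-removed
#'   series (gap-spanning differences included; flagged via `gap_spanning`).
#'
#' Percentiles interpolate linearly between order statistics
#' (`quantile(type = 7)`). A window with no local maxima (or minima) leaves
#' the corresponding size threshold unchanged.
#'
#' @param baseline Numeric vector of baseline-window samples; `NaN` marks
#'   missing data.
#' @param thresholds Current threshold list (as in [classify_phase()]).
#' @param config A [detector_config()].
#' @return A list: `thresholds` (possibly updated), `updated` (logical),
#'   `valid_fraction`, `gap_spanning` (logical, `TRUE` when the valid
#'   series had interior gaps so some differences span them).
#' @export
update_thresholds <- function(baseline, thresholds, config) {
  valid <- is.finite(baseline)
  vf <- mean(valid)
  if (vf < 0.5) {
    return(list(thresholds = thresholds, updated = FALSE,
                valid_fraction = vf, gap_spanning = FALSE))
  }
  y <- baseline[valid]
  y <- y - mean(y)
  th <- thresholds
  pk <- local_maxima(y)
  if (length(pk))
    th$peak_size <- unname(stats::quantile(y[pk], config$peak_percentile / 100,
                                           type = 7))
  tr <- local_maxima(-y)
  if (length(tr))
    th$trough_size <- unname(stats::quantile(y[tr],
                                             config$trough_percentile / 100,
                                             type = 7))
  if (length(y) > 1L) {
    d <- diff(y)
    th$dilation_derivative <-
      unname(stats::quantile(d, config$dilation_percentile / 100, type = 7))
    th$constriction_derivative <-
      unname(stats::quantile(d, config$constriction_percentile / 100,
                             type = 7))
  }
  gaps <- any(!valid) && any(diff(which(valid)) > 1L)
  list(thresholds = th, updated = TRUE, valid_fraction = vf,
       gap_spanning = gaps)
}

#' Schedule phase-independent (random) control events
#'
#' Event times are drawn without reference to pupil data as a renewal
#' process whose gaps are `inter_event_interval + Exponential(rate)`, so
#' consecutive random events always honour the IEI.
#'
#' @param span Recording duration in seconds.
#' @param rate Events per second (the exponential rate); 0 disables.
#' @param iei Minimum gap, seconds.
#' @param seed Optional integer seed (local to this call; the global RNG
#'   state is restored).
#' @return Numeric vector of event times in `(0, span]`.
#' @export
schedule_random_events <- function(span, rate, iei, seed = NULL) {
  if (rate <= 0 || span <= 0) return(numeric())
  runner <- function() {
    times <- numeric()
    t <- 0
    repeat {
      t <- t + iei + stats::rexp(1, rate)
      if (t > span) break
      times <- c(times, t)
    }
    times
  }
  if (is.null(seed)) return(runner())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runner()
}

# split raw samples into completed pupil-sample blocks; each sample carries
# the inter-sample interval ending at it (first interval backfilled), so at
# a fixed rate a 0.1 s block holds ceiling(0.1 * rate) points
assign_pupil_samples <- function(time_s, target) {
  n <- length(time_s)
  dt <- diff(time_s)
  dt <- if (n >= 2L) c(dt[1L], dt) else rep(target, n)
  block <- integer(n)
  acc <- 0
  b <- 1L
  for (i in seq_len(n)) {
    acc <- acc + dt[i]
    block[i] <- b
    if (acc >= target - .dur_eps) {
      acc <- 0
      b <- b + 1L
    }
  }
  # block b is either still accumulating or empty, so never complete
  list(block = block, dt = dt, n_complete = b - 1L)
}

translate_dialect <- function(values, dialect) {
  v <- as.numeric(values)
  v[!is.finite(v)] <- NaN
  switch(dialect,
         human = ,
         synthetic = {
           v[v == 0] <- NaN
           v
         },
         mouse = {
           v[v < 0] <- NaN
           v
         },
         monkey = v,
         stop("unknown dialect: ", dialect, call. = FALSE))
}

#' Run the streaming pupil-phase detector over a sample stream
#'
#' The four-stage pipeline: (1) raw samples are gathered into 0.1 s pupil
#' samples, with the dialect's missing sentinel translated to `NaN`;
#' (2) each pupil sample is appended to a search window and a baseline
#' window -- the search window is cleared whenever it contains a `NaN`, and
#' also once more after a window that did; (3) the NaN-free search window,
#' once it holds at least two pupil samples, is demeaned and fit with a
#' quadratic whose final value is recorded; (4) successive final values are
#' compared against adaptive pupil-size and derivative thresholds,
#' re-estimated from each filled baseline window with at least 50% valid
#' samples. Detections closer than the inter-event interval to the last
#' accepted event are logged as not accepted. Accepted detections clear the
#' search window; the window is also reset when it exceeds its maximum
#' duration. Random control events are scheduled independently of the data.
#'
#' @param stream Data frame with columns `time_s` (nondecreasing) and
#'   `pupil` (raw device units; the dialect's missing sentinel still
#'   present).
#' @param config A [detector_config()].
#' @param dialect Missing-data dialect: `"human"`/`"synthetic"` (0 means
#'   occluded), `"mouse"` (negative means occluded; locomotion is masked
#'   upstream), `"monkey"` (no sentinel; artifacts cleaned upstream).
#' @return An object of class `event_log`: a data frame with columns
#'   `time_s`, `kind` (`dilation`, `peak`, `constriction`, `trough`,
#'   `random`), `accepted`, `fitted_value`, `threshold_snapshot_id`, plus
#'   attributes `thresholds` (snapshot history) and `diagnostics`
#'   (fit-window durations, reset counters, gap flags).
#' @export
run_detector <- function(stream, config = detector_config(),
                         dialect = c("human", "synthetic", "mouse",
                                     "monkey")) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(stream),
            all(c("time_s", "pupil") %in% names(stream)))
  time_s <- as.numeric(stream$time_s)
  if (length(time_s) == 0L) return(empty_event_log())
  bad <- which(diff(time_s) < 0)
  if (length(bad)) {
    warning(sprintf("dropping %d non-monotone samples", length(bad)))
    keep <- !seq_along(time_s) %in% (bad + 1L)
    time_s <- time_s[keep]
    stream <- stream[keep, , drop = FALSE]
  }
  values <- translate_dialect(stream$pupil, dialect)

  asg <- assign_pupil_samples(time_s, config$pupil_sample_duration)
  nb <- asg$n_complete
  if (nb == 0L) return(empty_event_log())
  blocks_v <- split(values, asg$block)[seq_len(nb)]
  block_dur <- vapply(split(asg$dt, asg$block)[seq_len(nb)], sum, 0)
  block_end <- vapply(split(time_s, asg$block)[seq_len(nb)],
                      function(t) t[length(t)], 0)

  th <- list(peak_size = config$start_thresholds[1],
             trough_size = config$start_thresholds[2],
             dilation_derivative = config$start_thresholds[3],
             constriction_derivative = config$start_thresholds[4])
  snapshot_id <- 0L
  snaps <- list()

  sw <- numeric()
  sw_dur <- 0
  sw_n <- 0L
  prev_sw_had_nan <- FALSE
  bw <- numeric()
  bw_dur <- 0
  fv_prev <- NA_real_
  last_accepted <- c(dilation = -Inf, peak = -Inf, constriction = -Inf,
                     trough = -Inf)
  iei <- config$inter_event_interval

  # at most one event and one fit per pupil sample: preallocate
  ev_t <- numeric(nb); ev_k <- character(nb); ev_a <- logical(nb)
  ev_f <- numeric(nb); ev_s <- integer(nb); n_ev <- 0L
  fit_durations <- numeric(nb); n_fit <- 0L
  n_reset_nan <- 0L; n_reset_max <- 0L; n_reset_accept <- 0L
  gap_flags <- 0L

  for (b in seq_len(nb)) {
    pv <- blocks_v[[b]]
    bd <- block_dur[[b]]
    t_end <- block_end[[b]]

    # stage 2: windows
    bw <- c(bw, pv)
    bw_dur <- bw_dur + bd
    if (anyNA(pv)) {
      sw <- numeric(); sw_dur <- 0; sw_n <- 0L; fv_prev <- NA_real_
      prev_sw_had_nan <- TRUE
      n_reset_nan <- n_reset_nan + 1L
    } else if (prev_sw_had_nan) {
      sw <- numeric(); sw_dur <- 0; sw_n <- 0L; fv_prev <- NA_real_
      prev_sw_had_nan <- FALSE
    } else {
      sw <- c(sw, pv)
      sw_dur <- sw_dur + bd
      sw_n <- sw_n + 1L
    }

    # stage 3/4: fit and classify while the window is within bounds
    if (sw_dur > config$max_search_window_duration + .dur_eps) {
      sw <- numeric(); sw_dur <- 0; sw_n <- 0L; fv_prev <- NA_real_
      n_reset_max <- n_reset_max + 1L
    } else if (sw_n >= 2L) {
      fit <- fit_search_window(sw)
      n_fit <- n_fit + 1L
      fit_durations[n_fit] <- sw_dur
      fv <- fit$final_value
      if (is.finite(fv_prev)) {
        kind <- classify_phase(fv_prev, fv, th)
        if (!is.na(kind)) {
          ref <- if (config$iei_per_event_type) last_accepted[[kind]]
                 else max(last_accepted)
          ok <- (t_end - ref) > iei
          n_ev <- n_ev + 1L
          ev_t[n_ev] <- t_end; ev_k[n_ev] <- kind
          ev_a[n_ev] <- ok; ev_f[n_ev] <- fv
          ev_s[n_ev] <- snapshot_id
          if (ok) {
            last_accepted[[kind]] <- t_end
            sw <- numeric(); sw_dur <- 0; sw_n <- 0L; fv_prev <- NA_real_
            n_reset_accept <- n_reset_accept + 1L
          } else if (config$clear_on_rejected) {
            sw <- numeric(); sw_dur <- 0; sw_n <- 0L; fv_prev <- NA_real_
          }
        }
      }
      # a detection may have cleared the window; the next lineage then
      # needs two fits of its own before classification resumes
      fv_prev <- if (sw_n == 0L) NA_real_ else fv
    }

    # stage 4: threshold refresh from a filled baseline window
    if (bw_dur >= config$baseline_window_duration - .dur_eps) {
      up <- update_thresholds(bw, th, config)
      if (up$updated) {
        th <- up$thresholds
        snapshot_id <- snapshot_id + 1L
        if (up$gap_spanning) gap_flags <- gap_flags + 1L
        snaps[[snapshot_id]] <- data.frame(
          snapshot_id = snapshot_id, time_s = t_end,
          peak_size = th$peak_size, trough_size = th$trough_size,
          dilation_derivative = th$dilation_derivative,
          constriction_derivative = th$constriction_derivative,
          valid_fraction = up$valid_fraction,
          gap_spanning = up$gap_spanning)
      }
      bw <- numeric()
      bw_dur <- 0
    }
  }

  span <- time_s[length(time_s)]
  rt <- schedule_random_events(span, config$random_event_rate, iei,
                               config$rng_seed)
  keep <- seq_len(n_ev)
  log <- data.frame(
    time_s = c(ev_t[keep], rt),
    kind = c(ev_k[keep], rep("random", length(rt))),
    accepted = c(ev_a[keep], rep(TRUE, length(rt))),
    fitted_value = c(ev_f[keep], rep(NA_real_, length(rt))),
    threshold_snapshot_id = c(ev_s[keep], rep(NA_integer_, length(rt))),
    stringsAsFactors = FALSE)
  log <- log[order(log$time_s), , drop = FALSE]
  rownames(log) <- NULL
  attr(log, "thresholds") <- if (length(snaps))
    do.call(rbind, snaps) else NULL
  attr(log, "diagnostics") <- list(
    n_pupil_samples = nb,
    fit_durations = fit_durations[seq_len(n_fit)],
    resets = c(nan = n_reset_nan, max_duration = n_reset_max,
               accepted = n_reset_accept),
    gap_spanning_updates = gap_flags)
  class(log) <- c("event_log", "data.frame")
  log
}

empty_event_log <- function() {
  log <- data.frame(time_s = numeric(), kind = character(),
                    accepted = logical(), fitted_value = numeric(),
                    threshold_snapshot_id = integer(),
                    stringsAsFactors = FALSE)
  attr(log, "thresholds") <- NULL
  attr(log, "diagnostics") <- list(n_pupil_samples = 0L,
                                   fit_durations = numeric(),
                                   resets = c(nan = 0L, max_duration = 0L,
                                              accepted = 0L),
                                   gap_spanning_updates = 0L)
  class(log) <- c("event_log", "data.frame")
  log
}

#' @export
print.event_log <- function(x, ...) {
  ph <- x[x$kind != "random", , drop = FALSE]
  cat(sprintf("<event_log> %d phase events (%d accepted), %d random\n",
              nrow(ph), sum(ph$accepted), sum(x$kind == "random")))
  if (nrow(ph)) {
    tab <- table(factor(ph$kind[ph$accepted],
                        levels = c("dilation", "peak", "constriction",
                                   "trough")))
    cat("  accepted by kind:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
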