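#' Detector configuration
#'
#' Bundles every tunable parameter of the streaming pupil-phase detector:
#' window durations, the inter-event interval (IEI), the four percentile
#' levels used when thresholds are re-estimated from the baseline window,
#' and the rate of phase-independent (random) control events.
#'
#' Durations are judged on cumulative sample-interval time, so the detector
#' supports irregular online sampling rates; at a fixed rate a 0.1 s pupil
#' sample reduces to `ceiling(0.1 * rate)` points.
#'
#' @param pupil_sample_duration Seconds of data per ingestion unit
#'   (the "pupil sample").
#' @param max_search_window_duration Maximum cumulative duration of the
#'   search window before it is forcibly reset, seconds.
#' @param baseline_window_duration Seconds of data accumulated before the
#'   adaptive thresholds are re-estimated.
#' @param inter_event_interval Minimum spacing (seconds) between accepted
#'   events; shorter-spaced detections are logged but flagged not accepted.
#' @param peak_percentile,trough_percentile Percentile (0-100) of baseline
#'   local-maximum / local-minimum values used as pupil-size thresholds.
#' @param dilation_percentile,constriction_percentile Percentile (0-100) of
#'   the baseline successive-difference distribution used as derivative
#'   thresholds.
#' @param iei_per_event_type If `TRUE` the IEI is enforced within each event
#'   kind separately (monkey preset); if `FALSE` globally across kinds.
#' @param random_event_rate Rate parameter (events/s) of the exponential
#'   component of random-event gaps; gaps are `IEI + Exp(rate)`. Zero
#'   disables random events.
#' @param start_thresholds Numeric vector of startup thresholds
#'   `c(peak_size, trough_size, dilation_derivative,
#'   constriction_derivative)` in the device's arbitrary units, used until
#'   the first valid baseline update.
#' @param clear_on_rejected If `TRUE` (default), the search window is
#'   cleared after every detection, accepted or not, so each fit lineage
#'   starts fresh and the window stays responsive; `FALSE` retains the
#'   window after a detection that fails the IEI gate, letting it
#'   accumulate until an accepted event or the maximum duration.
#' @param rng_seed Optional integer seed governing random-event scheduling.
#'
#' @return An object of class `detector_config` (a named list).
#' @seealso [species_preset()] for the published parameter sets.
#' @export
detector_config <- function(pupil_sample_duration = 0.1,
                            max_search_window_duration = 5,
                            baseline_window_duration = 5,
                            inter_event_interval = 3,
                            peak_percentile = 75,
                            trough_percentile = 25,
                            dilation_percentile = 99,
                            constriction_percentile = 1,
                            iei_per_event_type = FALSE,
                            random_event_rate = 1 / 3,
                            start_thresholds = c(0, 0, 50, -50),
                            clear_on_rejected = TRUE,
                            rng_seed = NULL) {
  cfg <- list(
    pupil_sample_duration = pupil_sample_duration,
    max_search_window_duration = max_search_window_duration,
    baseline_window_duration = baseline_window_duration,
    inter_event_interval = inter_event_interval,
    peak_percentile = peak_percentile,
    trough_percentile = trough_percentile,
    dilation_percentile = dilation_percentile,
    constriction_percentile = constriction_percentile,
    iei_per_event_type = isTRUE(iei_per_event_type),
    random_event_rate = random_event_rate,
    start_thresholds = start_thresholds,
    clear_on_rejected = isTRUE(clear_on_rejected),
    rng_seed = rng_seed
  )
  class(cfg) <- "detector_config"
  validate_detector_config(cfg)
  cfg
}

validate_detector_config <- function(cfg) {
  durs <- c(cfg$pupil_sample_duration, cfg$max_search_window_duration,
            cfg$baseline_window_duration)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("window durations must be positive and finite", call. = FALSE)
  if (cfg$inter_event_interval < 0)
    stop("inter_event_interval must be >= 0", call. = FALSE)
  pct <- c(cfg$peak_percentile, cfg$trough_percentile,
           cfg$dilation_percentile, cfg$constriction_percentile)
  if (any(pct < 0) || any(pct > 100))
    stop("percentiles must lie in [0, 100]", call. = FALSE)
  if (cfg$dilation_percentile <= cfg$constriction_percentile)
    stop("dilation_percentile must exceed constriction_percentile",
         call. = FALSE)
  if (cfg$peak_percentile <= cfg$trough_percentile)
    stop("peak_percentile must exceed trough_percentile", call. = FALSE)
  if (cfg$random_event_rate < 0)
    stop("random_event_rate must be >= 0", call. = FALSE)
  if (length(cfg$start_thresholds) != 4L ||
      any(!is.finite(cfg$start_thresholds)))
    stop("start_thresholds must be 4 finite numbers", call. = FALSE)
  invisible(cfg)
}

#' Species presets for the detector and replay simulator
#'
#' Published parameter sets per recording context. All presets share the
#' 0.1 s pupil sample, 5 s maximum search window, and the 75/25/99/1
#' percentile levels; they differ in baseline-window duration, IEI and its
#' scope, and the nominal online sampling rate.
#'
#' * `human`: ~60 Hz online rate, 5 s baseline, 3 s global IEI. Offline
#'   human recordings at 1000 Hz are decimated to 60 Hz before replay.
#' * `mouse`: ~20 Hz, 5 s baseline, 1 s global IEI; locomotion-concurrent
#'   and negative samples must be masked to `NaN` upstream.
#' * `monkey`: 1000 Hz, 0.5 s baseline, 1.5 s IEI enforced per event type,
#'   suited to short (<10 s) trial segments.
#'
#' @param species One of `"human"`, `"mouse"`, `"monkey"`, `"synthetic"`
#'   (`synthetic` equals `human` but expects no resampling).
#' @param ... Overrides forwarded to [detector_config()]; explicit values
#'   win over preset values.
#' @return A list with elements `name`, `online_rate_hz`, and `config`
#'   (a `detector_config`).
#' @export
species_preset <- function(species = c("human", "mouse", "monkey",
                                       "synthetic"), ...) {
  species <- match.arg(species)
  base <- switch(species,
    human = list(online_rate_hz = 60,
                 args = list(baseline_window_duration = 5,
                             inter_event_interval = 3,
                             iei_per_event_type = FALSE)),
    synthetic = list(online_rate_hz = 60,
                     args = list(baseline_window_duration = 5,
                                 inter_event_interval = 3,
                                 iei_per_event_type = FALSE)),
    mouse = list(online_rate_hz = 20,
                 args = list(baseline_window_duration = 5,
                             inter_event_interval = 1,
                             iei_per_event_type = FALSE)),
    monkey = list(online_rate_hz = 1000,
                  args = list(baseline_window_duration = 0.5,
                              inter_event_interval = 1.5,
                              iei_per_event_type = TRUE))
  )
  args <- utils::modifyList(base$args, list(...))
  list(name = species,
       online_rate_hz = base$online_rate_hz,
       config = do.call(detector_config, args))
}

#' @export
print.detector_config <- function(x, ...) {
  cat("<detector_config>\n")
  cat(sprintf("  pupil sample %.3g s | search <= %.3g s | baseline %.3g s\n",
              x$pupil_sample_duration, x$max_search_window_duration,
              x$baseline_window_duration))
  cat(sprintf("  IEI %.3g s (%s) | random rate %.3g /s\n",
              x$inter_event_interval,
              if (x$iei_per_event_type) "per event type" else "global",
              x$random_event_rate))
  cat(sprintf("  percentiles: peak %g / trough %g / dilation %g / constriction %g\n",
              x$peak_percentile, x$trough_percentile,
              x$dilation_percentile, x$constriction_percentile))
  cat(sprintf("  startup thresholds: %s\n",
              paste(format(x$start_thresholds), collapse = ", ")))
  invisible(x)
}
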