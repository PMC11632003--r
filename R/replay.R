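#' Decimate a recorded series to an emulated online rate
#'
#' Offline recordings (e.g. 1000 Hz) are reduced to the online acquisition
#' rate the detector would have seen live (e.g. ~60 Hz) by pure index
#' decimation -- every `k`-th sample with `k = round(offline/online)` --
#' because the goal is emulating the online sampling, not anti-aliased
#' signal fidelity. Timestamps of the selected samples are preserved.
#'
#' @param series Data frame with `time_s` and `pupil` (extra columns kept).
#' @param offline_rate,online_rate Sampling rates in Hz;
#'   `online_rate <= offline_rate` (no upsampling).
#' @return The decimated data frame.
#' @export
resample_to_online_rate <- function(series, offline_rate, online_rate) {
  if (online_rate > offline_rate)
    stop("online_rate must not exceed offline_rate (no upsampling)",
         call. = FALSE)
  k <- round(offline_rate / online_rate)
  if (k <= 1L) return(series)
  idx <- seq(1L, nrow(series), by = k)
  out <- series[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask locomotion-concurrent and negative mouse pupil samples
#'
#' Samples concurrent with a locomotion event, or with a negative value
#' (blinking/whisking artifacts), are replaced with `NaN`. Idempotent.
#'
#' @param values Numeric pupil vector.
#' @param locomotion Binary vector of the same length (1 = locomotion), or
#'   `NULL` for none.
#' @return Numeric vector with masked positions set to `NaN`.
#' @export
mask_mouse_artifacts <- function(values, locomotion = NULL) {
  v <- as.numeric(values)
  if (!is.null(locomotion)) {
    if (length(locomotion) != length(v))
      stop("locomotion vector length must match the series", call. = FALSE)
    v[locomotion != 0] <- NaN
  }
  v[!is.na(v) & v < 0] <- NaN
  v
}

#' Select monkey trial segments long enough for detection
#'
#' @param segments Data frame with `start_s`, `end_s` (optionally
#'   `trial_id`).
#' @param min_duration Seconds; only segments strictly longer are kept.
#' @return The qualifying rows.
#' @export
select_monkey_trials <- function(segments, min_duration = 5) {
  if (is.null(segments) || nrow(segments) == 0L) return(segments)
  keep <- (segments$end_s - segments$start_s) > min_duration
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replay a recorded pupil series through the streaming detector
#'
#' The offline simulator: applies the dialect's preprocessing, emulates the
#' online sampling rate where the preset requires it, and streams the
#' result through [run_detector()] -- the identical code path used live.
#'
#' * `human`: decimated from `offline_rate_hz` to the preset's online rate
#'   when the recording is faster; zero values become `NaN` at ingest.
#' * `synthetic`: as human, typically already at the online rate.
#' * `mouse`: locomotion-concurrent and negative samples masked to `NaN`
#'   first; no resampling (recordings are at ~20 Hz).
#' * `monkey`: trial segments longer than 5 s are selected, each segment is
#'   artifact-cleaned by interpolation ([preprocess_pupil()]), and the
#'   detector runs per segment with windows, thresholds and IEI state reset
#'   between trials (trials are noncontiguous).
#'
#' Trackers filter their saved (file) traces more heavily than the
#' real-time link stream the live detector sees. `online_noise_sd` emulates
#' that difference by adding white acquisition jitter to the replayed
#' human/synthetic stream after decimation (missing-sentinel zeros are left
#' untouched); the default 0 replays the recording verbatim.
#'
#' @param recording A `pupil_recording` (see [read_recording()],
#'   [generate_unrest()]).
#' @param preset A [species_preset()] list (or its name).
#' @param offline_rate_hz Recording rate when it differs from the preset's
#'   online rate (human replay); `NULL` means already at the online rate.
#' @param online_noise_sd Link-stream jitter SD in device units (human and
#'   synthetic dialects only), seeded from the preset config's `rng_seed`.
#' @return An `event_log`; monkey logs carry a `segment` column.
#' @export
replay <- function(recording, preset = species_preset("human"),
                   offline_rate_hz = NULL, online_noise_sd = 0) {
  if (is.character(preset)) preset <- species_preset(preset)
  cfg <- preset$config
  dialect <- recording$dialect
  series <- recording$data
  if (is.null(series) || nrow(series) == 0L) return(empty_event_log())

  if (dialect %in% c("human", "synthetic") && !is.null(offline_rate_hz) &&
      offline_rate_hz > preset$online_rate_hz) {
    series <- resample_to_online_rate(series, offline_rate_hz,
                                      preset$online_rate_hz)
  }
  if (dialect %in% c("human", "synthetic") && online_noise_sd > 0) {
    # offset so the jitter stream differs from the random-event stream
    if (!is.null(cfg$rng_seed))
      set.seed((cfg$rng_seed + 104729L) %% 2147483647L)
    jit <- stats::rnorm(nrow(series), 0, online_noise_sd)
    keep0 <- !is.na(series$pupil) & series$pupil == 0
    series$pupil <- series$pupil + jit
    series$pupil[keep0] <- 0
  }

  if (dialect == "mouse") {
    series$pupil <- mask_mouse_artifacts(series$pupil,
                                         recording$locomotion)
    return(run_detector(series, cfg, dialect = "mouse"))
  }

  if (dialect == "monkey") {
    segs <- select_monkey_trials(recording$segments, min_duration = 5)
    if (is.null(segs) || nrow(segs) == 0L) return(empty_event_log())
    rate <- preset$online_rate_hz
    logs <- lapply(seq_len(nrow(segs)), function(i) {
      sel <- series$time_s >= segs$start_s[i] &
        series$time_s <= segs$end_s[i]
      seg <- series[sel, , drop = FALSE]
      if (nrow(seg) < 2L) return(NULL)
      # per-trial artifact cleaning before detection
      pp <- preprocess_pupil(seg$pupil, rate)
      seg$pupil <- pp$values
      log <- run_detector(seg, cfg, dialect = "monkey")
      if (nrow(log)) log$segment <- if (!is.null(segs$trial_id))
        segs$trial_id[i] else i
      log
    })
    logs <- Filter(function(l) !is.null(l) && nrow(l) > 0, logs)
    if (!length(logs)) return(empty_event_log())
    out <- do.call(rbind, lapply(logs, as.data.frame))
    rownames(out) <- NULL
    class(out) <- c("event_log", "data.frame")
    return(out)
  }

  run_detector(series, cfg, dialect = dialect)
}
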