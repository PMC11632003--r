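#' Construct a pupil recording object
#'
#' @param data Data frame with numeric `time_s` (nondecreasing) and
#'   `pupil`.
#' @param dialect One of `"human"`, `"mouse"`, `"monkey"`, `"synthetic"`.
#' @param segments Optional data frame of monkey trial bounds
#'   (`start_s`, `end_s`, optionally `trial_id`), non-overlapping and
#'   time-ordered.
#' @param locomotion Optional binary vector aligned to `data` (mouse).
#' @return A `pupil_recording` list.
#' @export
pupil_recording <- function(data, dialect = "human", segments = NULL,
                            locomotion = NULL) {
  stopifnot(is.data.frame(data),
            all(c("time_s", "pupil") %in% names(data)))
  if (!is.numeric(data$time_s) || !is.numeric(data$pupil))
    stop("time_s and pupil must be numeric", call. = FALSE)
  if (is.unsorted(data$time_s))
    stop("time_s must be nondecreasing", call. = FALSE)
  if (!is.null(locomotion) && length(locomotion) != nrow(data))
    stop("locomotion must align with the series", call. = FALSE)
  if (!is.null(segments)) {
    o <- order(segments$start_s)
    s <- segments[o, , drop = FALSE]
    if (any(s$end_s < s$start_s) ||
        (nrow(s) > 1 && any(s$start_s[-1] < s$end_s[-nrow(s)])))
      stop("segments must be non-overlapping and time-ordered",
           call. = FALSE)
    segments <- s
  }
  rec <- list(data = data, dialect = dialect, segments = segments,
              locomotion = locomotion,
              params = list(rate_hz = estimate_rate(data$time_s)))
  class(rec) <- "pupil_recording"
  rec
}

estimate_rate <- function(time_s) {
  if (length(time_s) < 2L) return(NA_real_)
  1 / stats::median(diff(time_s))
}

#' Read a pupil recording from CSV
#'
#' Expects columns `time_s` and `pupil` (optionally `locomotion`); an
#' optional trials CSV supplies `trial_id`, `start_s`, `end_s` segment
#' bounds for the monkey dialect. Dialect sentinel rules (0/negative ->
#' `NaN`) are applied at detector ingest, not here.
#'
#' @param path Recording CSV path.
#' @param dialect Missing-data dialect of the file.
#' @param trials_path Optional trials CSV path.
#' @return A `pupil_recording`.
#' @export
read_recording <- function(path, dialect = "human", trials_path = NULL) {
  df <- utils::read.csv(path)
  for (col in c("time_s", "pupil")) {
    if (!col %in% names(df))
      stop("recording file is missing required column '", col, "'",
           call. = FALSE)
    if (!is.numeric(df[[col]]))
      stop("column '", col, "' must be numeric", call. = FALSE)
  }
  if (is.unsorted(df$time_s))
    stop("time_s must be sorted nondecreasing", call. = FALSE)
  segments <- NULL
  if (!is.null(trials_path)) {
    segments <- utils::read.csv(trials_path)
    need <- c("start_s", "end_s")
    if (!all(need %in% names(segments)))
      stop("trials file must have columns start_s, end_s", call. = FALSE)
  }
  locomotion <- if ("locomotion" %in% names(df)) df$locomotion else NULL
  pupil_recording(df[c("time_s", "pupil")], dialect = dialect,
                  segments = segments, locomotion = locomotion)
}

#' Write a pupil recording (and optional ground-truth sidecar) to disk
#'
#' @param recording A `pupil_recording`.
#' @param path CSV destination.
#' @param sidecar Optional JSON path; written when the recording carries
#'   analytic ground truth (extrema times and generator parameters).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, sidecar = NULL) {
  df <- recording$data
  if (!is.null(recording$locomotion)) df$locomotion <- recording$locomotion
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(sidecar) && !is.null(recording$truth)) {
    p <- recording$params
    jsonlite::write_json(
      list(peak_times = recording$truth$peak_times,
           trough_times = recording$truth$trough_times,
           rate_hz = p$rate_hz, duration_s = p$duration_s,
           components = p$components,
           drift_sd = p$drift_sd, noise_sd = p$noise_sd,
           blink_rate = p$blink_rate, seed = p$seed),
      sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write / read an event log CSV
#'
#' Columns: `time_s`, `kind`, `accepted`, `fitted_value`,
#' `threshold_snapshot_id` (plus `segment` for monkey replays).
#'
#' @param log An `event_log`.
#' @param path CSV path.
#' @return `path` invisibly (write); an `event_log` (read).
#' @export
write_event_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("event_log", "data.frame")
  df
}
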