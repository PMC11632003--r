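#' Accuracy of detected events against a true phase index
#'
#' Each event time is mapped to its sample index; the accuracy is the
#' percentage of events landing on a 1 in the binary index.
#'
#' @param event_times Event times in seconds (accepted events only for
#'   accuracy reporting).
#' @param index 0/1 vector over the recording.
#' @param rate_hz Sampling rate, Hz.
#' @param t0 Time of the first sample (default 0).
#' @return Percentage in `[0, 100]`, or `NA_real_` with zero events.
#' @export
event_accuracy <- function(event_times, index, rate_hz, t0 = 0) {
  if (!length(event_times)) return(NA_real_)
  i <- round((event_times - t0) * rate_hz) + 1L
  i <- i[i >= 1L & i <= length(index)]
  if (!length(i)) return(NA_real_)
  100 * mean(index[i] == 1L)
}

.phase_kinds <- c("dilation", "peak", "constriction", "trough")

#' Detected-kind by true-kind sensitivity matrix
#'
#' Accepted events of each detected kind (plus the random control row) are
#' scored against each of the four true phase indices. The diagonal is the
#' on-target accuracy; off-diagonal entries quantify phase overlap and
#' detector confusion.
#'
#' @param log An `event_log`.
#' @param truth List with `dilation_index`, `peak_index`,
#'   `constriction_index`, `trough_index`.
#' @param rate_hz Sampling rate, Hz.
#' @param t0 Time of the first sample.
#' @return 5 x 4 numeric matrix, rows `dilation, peak, constriction,
#'   trough, random`, columns the true kinds.
#' @export
sensitivity_matrix <- function(log, truth, rate_hz, t0 = 0) {
  idx <- list(dilation = truth$dilation_index,
              peak = truth$peak_index,
              constriction = truth$constriction_index,
              trough = truth$trough_index)
  rows <- c(.phase_kinds, "random")
  m <- matrix(NA_real_, length(rows), 4L,
              dimnames = list(detected = rows, true = .phase_kinds))
  for (r in rows) {
    tt <- log$time_s[log$kind == r & log$accepted]
    for (cc in .phase_kinds)
      m[r, cc] <- event_accuracy(tt, idx[[cc]], rate_hz, t0)
  }
  m
}

#' Group accuracy and sensitivity tests
#'
#' Two families of four tests, each Holm-Bonferroni adjusted within its
#' family:
#' * accuracy: paired t-test per phase of on-target accuracy versus the
#'   random-event baseline against the same true index, across subjects;
#' * sensitivity: one-sample t-test per phase of the per-subject
#'   (on-target minus mean off-target) difference against zero.
#'
#' Subjects with undefined values (no events of a kind) are dropped
#' pairwise. Zero-variance differences yield a degenerate p (0 when the
#' mean difference is nonzero, 1 otherwise) with a warning.
#'
#' @param matrices List of per-subject 5 x 4 matrices from
#'   [sensitivity_matrix()].
#' @return List of two data frames `accuracy` and `sensitivity` with
#'   columns `phase`, `mean_on`, `mean_ref`, `t`, `df`, `p`, `p_holm`.
#' @export
accuracy_tests <- function(matrices) {
  stopifnot(length(matrices) >= 2L)
  one_family <- function(on, ref) {
    res <- lapply(seq_along(.phase_kinds), function(k) {
      d <- on[, k] - ref[, k]
      ok <- is.finite(d)
      d <- d[ok]
      if (length(d) < 2L)
        return(data.frame(phase = .phase_kinds[k], mean_on = NA, mean_ref = NA,
                          t = NA, df = NA, p = NA))
      if (stats::sd(d) <= .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
        warning("zero-variance difference for phase ", .phase_kinds[k],
                "; degenerate p reported")
        p <- if (mean(d) == 0) 1 else 0
        tval <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      } else {
        tt <- stats::t.test(d)
        p <- tt$p.value
        tval <- unname(tt$statistic)
      }
      data.frame(phase = .phase_kinds[k],
                 mean_on = mean(on[ok, k]), mean_ref = mean(ref[ok, k]),
                 t = tval, df = length(d) - 1L, p = p)
    })
    out <- do.call(rbind, res)
    out$p_holm <- stats::p.adjust(out$p, method = "holm")
    out
  }
  on <- t(vapply(matrices, function(m) diag(m[.phase_kinds, ]),
                 numeric(4)))
  rnd <- t(vapply(matrices, function(m) m["random", ], numeric(4)))
  off <- t(vapply(matrices, function(m)
    vapply(seq_len(4), function(k) mean(m[k, -k]), 0), numeric(4)))
  list(accuracy = one_family(on, rnd),
       sensitivity = one_family(on, off))
}

#' Temporal performance of the detector
#'
#' Pools all detected phase events -- accepted or not, random events
#' excluded -- sorts them, and takes successive inter-event durations t'
#' within recording blocks only (differences spanning block gaps are
#' dropped). Reports the per-subject median, the group median across
#' subjects, the detection rate `1 / group median`, and the t'
#' distribution binned in 0.1 s increments up to 2 s.
#'
#' @param logs A single `event_log` or a list of per-subject logs.
#' @param block_bounds Optional data frame `start_s`, `end_s` per block
#'   (shared across subjects); `NULL` treats each recording as one block.
#' @return List: `per_subject_median`, `group_median_s`,
#'   `detection_rate_hz`, `histogram` (data frame `bin_start_s`,
#'   `fraction`), `fraction_below_0.1`, `t_prime` (pooled values).
#' @export
temporal_performance <- function(logs, block_bounds = NULL) {
  if (inherits(logs, "event_log") || is.data.frame(logs)) logs <- list(logs)
  subj <- lapply(logs, function(log) {
    tt <- sort(log$time_s[log$kind != "random"])
    if (length(tt) < 2L) return(numeric())
    if (is.null(block_bounds)) return(diff(tt))
    blk <- findInterval(tt, block_bounds$start_s)
    inside <- tt <= block_bounds$end_s[pmax(blk, 1L)] & blk >= 1L
    tt <- tt[inside]
    blk <- blk[inside]
    d <- diff(tt)
    d[diff(blk) == 0]
  })
  med <- vapply(subj, function(d) if (length(d)) stats::median(d)
                else NA_real_, 0)
  gm <- stats::median(med, na.rm = TRUE)
  tp <- unlist(subj)
  bins <- seq(0, 2, by = 0.1)
  hist_frac <- if (length(tp)) {
    counts <- vapply(bins, function(b)
      sum(tp >= b & tp < b + 0.1), 0L)
    counts / length(tp)
  } else rep(NA_real_, length(bins))
  list(per_subject_median = med,
       group_median_s = gm,
       detection_rate_hz = if (is.finite(gm) && gm > 0)
         detection_rate(gm) else NA_real_,
       histogram = data.frame(bin_start_s = bins, fraction = hist_frac),
       fraction_below_0.1 = if (length(tp)) mean(tp < 0.1) else NA_real_,
       t_prime = tp)
}

#' Detection rate from a median inter-event duration
#'
#' @param median_t_prime_s Group median inter-event duration, seconds.
#' @return Rate in Hz (`1 / median`).
#' @export
detection_rate <- function(median_t_prime_s) {
  stopifnot(median_t_prime_s > 0)
  1 / median_t_prime_s
}
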