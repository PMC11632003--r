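# Independent oracles used to cross-check the streaming implementation.
# Written deliberately in a different style: windows are recomputed from
# index ranges into the full recording at every step, fits use lm(), and
# percentiles / local extrema are computed by hand-rolled scans.

# linear-interpolation percentile between order statistics (brute force)
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# strict local maxima with plateau-first-index rule, by forward scan
oracle_local_maxima <- function(y) {
  n <- length(y)
  out <- integer()
  i <- 2L
  while (i < n) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# prominence by exhaustive interval minima
oracle_prominence <- function(y, p) {
  n <- length(y)
  higher_left <- which(y[seq_len(p - 1)] > y[p])
  lo <- if (length(higher_left)) max(higher_left) else 1L
  higher_right <- which(y[(p + 1):n] > y[p])
  hi <- if (length(higher_right)) p + min(higher_right) else n
  y[p] - max(min(y[lo:p]), min(y[p:hi]))
}

# full re-implementation of the four-stage decision sequence, operating on
# the complete recording with index bookkeeping instead of growing buffers
oracle_detector <- function(stream, config, dialect = "synthetic") {
  v <- as.numeric(stream$pupil)
  if (dialect %in% c("human", "synthetic")) v[v == 0] <- NaN
  if (dialect == "mouse") v[!is.na(v) & v < 0] <- NaN
  v[!is.finite(v)] <- NaN
  tm <- as.numeric(stream$time_s)
  n <- length(tm)
  dts <- c(if (n >= 2L) tm[2] - tm[1] else config$pupil_sample_duration,
           diff(tm))

  # pupil-sample boundaries by cumulative interval time
  blocks <- list()
  cur <- integer()
  acc <- 0
  for (i in seq_len(n)) {
    cur <- c(cur, i)
    acc <- acc + dts[i]
    if (acc >= config$pupil_sample_duration - 1e-9) {
      blocks[[length(blocks) + 1L]] <- cur
      cur <- integer()
      acc <- 0
    }
  }

  fit_final <- function(idx) {
    y <- v[idx] - mean(v[idx])
    m <- length(idx)
    if (m <= 3L) return(y[m])
    x <- 0:(m - 1)
    co <- stats::coef(stats::lm(y ~ x + I(x^2)))
    unname(co[1] + co[2] * (m - 1) + co[3] * (m - 1)^2)
  }

  th <- list(peak_size = config$start_thresholds[1],
             trough_size = config$start_thresholds[2],
             dilation_derivative = config$start_thresholds[3],
             constriction_derivative = config$start_thresholds[4])

  sw_blocks <- integer()      # indices into `blocks`
  sw_dur <- 0
  bw_blocks <- integer()
  bw_dur <- 0
  prev_nan <- FALSE
  fv_prev <- NA_real_
  last_acc <- c(dilation = -Inf, peak = -Inf, constriction = -Inf,
                trough = -Inf)
  ev <- list()

  clear_sw <- function() {
    sw_blocks <<- integer(); sw_dur <<- 0; fv_prev <<- NA_real_
  }

  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    bd <- sum(dts[idx])
    t_end <- tm[idx[length(idx)]]
    bw_blocks <- c(bw_blocks, b)
    bw_dur <- bw_dur + bd
    if (anyNA(v[idx])) {
      clear_sw()
      prev_nan <- TRUE
    } else if (prev_nan) {
      clear_sw()
      prev_nan <- FALSE
    } else {
      sw_blocks <- c(sw_blocks, b)
      sw_dur <- sw_dur + bd
    }

    if (sw_dur > config$max_search_window_duration + 1e-9) {
      clear_sw()
    } else if (length(sw_blocks) >= 2L) {
      widx <- unlist(blocks[sw_blocks])
      fv <- fit_final(widx)
      if (is.finite(fv_prev)) {
        kind <- NA_character_
        if (fv < fv_prev && fv > th$peak_size) kind <- "peak"
        else if (fv > fv_prev && fv < th$trough_size) kind <- "trough"
        else if (fv - fv_prev > th$dilation_derivative) kind <- "dilation"
        else if (fv - fv_prev < th$constriction_derivative)
          kind <- "constriction"
        if (!is.na(kind)) {
          ref <- if (config$iei_per_event_type) last_acc[[kind]]
                 else max(last_acc)
          ok <- (t_end - ref) > config$inter_event_interval
          ev[[length(ev) + 1L]] <- data.frame(
            time_s = t_end, kind = kind, accepted = ok, fitted_value = fv)
          if (ok) {
            last_acc[[kind]] <- t_end
            clear_sw()
          } else if (config$clear_on_rejected) clear_sw()
        }
        if (length(sw_blocks)) fv_prev <- fv
      } else fv_prev <- fv
    }

    if (bw_dur >= config$baseline_window_duration - 1e-9) {
      bv <- v[unlist(blocks[bw_blocks])]
      if (mean(is.finite(bv)) >= 0.5) {
        y <- bv[is.finite(bv)]
        y <- y - mean(y)
        pk <- oracle_local_maxima(y)
        if (length(pk))
          th$peak_size <- oracle_percentile(y[pk], config$peak_percentile)
        tr <- oracle_local_maxima(-y)
        if (length(tr))
          th$trough_size <- oracle_percentile(y[tr],
                                              config$trough_percentile)
        dd <- diff(y)
        th$dilation_derivative <-
          oracle_percentile(dd, config$dilation_percentile)
        th$constriction_derivative <-
          oracle_percentile(dd, config$constriction_percentile)
      }
      bw_blocks <- integer()
      bw_dur <- 0
    }
  }
  if (!length(ev))
    return(data.frame(time_s = numeric(), kind = character(),
                      accepted = logical(), fitted_value = numeric()))
  do.call(rbind, ev)
}
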