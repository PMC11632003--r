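test_that("pupil samples complete on cumulative interval time", {
  # 6 samples at 1/60 s intervals carry exactly 0.1 s of data
  t6 <- (0:5) / 60
  log <- run_detector(data.frame(time_s = t6, pupil = rep(3000, 6)),
                      detector_config(random_event_rate = 0))
  expect_identical(attr(log, "diagnostics")$n_pupil_samples, 1L)

  # 5 samples spanning 0.083 s stay below the 0.1 s target
  t5 <- (0:4) / 60
  log5 <- run_detector(data.frame(time_s = t5, pupil = rep(3000, 5)),
                       detector_config(random_event_rate = 0))
  expect_identical(attr(log5, "diagnostics")$n_pupil_samples, 0L)
})

test_that("the human dialect translates zeros to missing and clears windows", {
  # one blinked block, then clean blocks; the first clean block after the
  # NaN window is discarded too, so no fit can see a NaN
  v <- rep(3000, 60)
  v[7:12] <- 0
  log <- run_detector(data.frame(time_s = (0:59) / 60, pupil = v),
                      detector_config(random_event_rate = 0))
  d <- attr(log, "diagnostics")
  expect_gte(d$resets[["nan"]], 1L)
  expect_identical(nrow(log), 0L)  # constant data never classifies
})

test_that("non-monotone timestamps are dropped with a warning", {
  df <- data.frame(time_s = c(0, 1, 0.5, 2) / 10, pupil = rep(3000, 4))
  expect_warning(run_detector(df, detector_config(random_event_rate = 0)),
                 "non-monotone")
})

test_that("quadratic window fits match closed-form expectations", {
  expect_equal(fit_search_window(rep(2, 6))$final_value, 0)
  # exact quadratic x^2 on 0..5: demeaned final value = 25 - 55/6
  expect_equal(fit_search_window(c(0, 1, 4, 9, 16, 25))$final_value,
               95 / 6, tolerance = 1e-9)
  # 3-point interpolation of [0,1,0]
  expect_equal(fit_search_window(c(0, 1, 0))$final_value, -1 / 3)
  expect_error(fit_search_window(c(1, NaN, 2)), "NaN")
  expect_error(fit_search_window(3), ">= 2")
})

test_that("fits reproduce any exact quadratic at the last abscissa", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:300, 1)
    co <- stats::rnorm(3, sd = c(1000, 50, 1))
    x <- 0:(n - 1)
    y <- co[1] + co[2] * x + co[3] * x^2
    expect_equal(fit_search_window(y)$final_value,
                 (y - mean(y))[n], tolerance = 1e-9)
  }
})

test_that("phase classification applies the documented rule precedence", {
  th <- list(peak_size = 0, trough_size = 0, dilation_derivative = 50,
             constriction_derivative = -50)
  expect_identical(classify_phase(5, 4, th), "peak")
  expect_identical(classify_phase(0, 60, th), "dilation")
  expect_identical(classify_phase(0, 10, th), NA_character_)
  # trough and dilation both satisfied: trough wins by precedence
  expect_identical(classify_phase(-100, -10, th), "trough")
  # peak and constriction both satisfied: peak wins
  expect_identical(classify_phase(100, 10, th), "peak")
  expect_identical(classify_phase(NaN, 1, th), NA_character_)
})

test_that("baseline threshold updates match the brute-force oracle", {
  cfg <- detector_config()
  th0 <- list(peak_size = 0, trough_size = 0, dilation_derivative = 50,
              constriction_derivative = -50)
  y <- c(0, 1, 0, -1, 0, 2, 0, -2, 0)
  up <- update_thresholds(y, th0, cfg)
  expect_true(up$updated)
  expect_equal(up$thresholds$peak_size,
               oracle_percentile(c(1, 2), 75))          # 1.75
  expect_equal(up$thresholds$trough_size,
               oracle_percentile(c(-1, -2), 25))        # -1.75
  expect_equal(up$thresholds$dilation_derivative,
               oracle_percentile(diff(y), 99))          # ~2
  expect_equal(up$thresholds$constriction_derivative,
               oracle_percentile(diff(y), 1))           # ~-2

  # randomized cross-check of the percentile path
  set.seed(7)
  for (i in 1:10) {
    z <- stats::rnorm(200)
    u <- update_thresholds(z, th0, cfg)
    zz <- z - mean(z)
    pk <- oracle_local_maxima(zz)
    expect_equal(u$thresholds$peak_size, oracle_percentile(zz[pk], 75))
    expect_equal(u$thresholds$dilation_derivative,
                 oracle_percentile(diff(zz), 99))
  }
})

test_that("invalid or degenerate baselines leave thresholds untouched", {
  cfg <- detector_config()
  th0 <- list(peak_size = 10, trough_size = -10,
              dilation_derivative = 50, constriction_derivative = -50)
  y <- c(1, 2, 3, NaN, NaN, NaN, NaN, NaN, NaN, 4)  # 60% missing
  up <- update_thresholds(y, th0, cfg)
  expect_false(up$updated)
  expect_identical(up$thresholds, th0)

  # monotone ramp: no extrema, size thresholds kept; derivatives = slope
  ramp <- seq(0, 9)
  up2 <- update_thresholds(ramp, th0, cfg)
  expect_true(up2$updated)
  expect_identical(up2$thresholds$peak_size, 10)
  expect_identical(up2$thresholds$trough_size, -10)
  expect_equal(up2$thresholds$dilation_derivative, 1)
  expect_equal(up2$thresholds$constriction_derivative, 1)
})

test_that("gap-spanning baselines are flagged in the update", {
  cfg <- detector_config()
  th0 <- list(peak_size = 0, trough_size = 0, dilation_derivative = 50,
              constriction_derivative = -50)
  y <- c(1, 2, NaN, 1, 3, 1, 2, 1, 4, 1)
  expect_true(update_thresholds(y, th0, cfg)$gap_spanning)
  expect_false(update_thresholds(y[!is.na(y)], th0, cfg)$gap_spanning)
})

test_that("local maxima use strict comparison with plateau-first-index", {
  expect_identical(local_maxima(c(0, 1, 0)), 2L)
  expect_identical(local_maxima(c(0, 1, 1, 0)), 2L)     # plateau start
  expect_identical(local_maxima(c(1, 1, 1)), integer())
  expect_identical(local_maxima(seq_len(5)), integer())
  set.seed(3)
  z <- stats::rnorm(500)
  expect_identical(local_maxima(z), oracle_local_maxima(z))
})

test_that("random events honour the IEI and are seed-reproducible", {
  expect_length(schedule_random_events(60, 0, 3), 0)
  a <- schedule_random_events(60, 0.2, 3, seed = 11)
  b <- schedule_random_events(60, 0.2, 3, seed = 11)
  expect_identical(a, b)
  expect_true(all(diff(a) >= 3))
  expect_true(all(a > 0 & a <= 60))
  # short span: zero or one event
  expect_lte(length(schedule_random_events(2, 5, 3, seed = 1)), 1L)
})

test_that("IEI gating separates accepted events globally or per kind", {
  p <- unrest_params(duration_s = 60, rate_hz = 60, seed = 21)
  rec <- generate_unrest(p)
  for (per_type in c(FALSE, TRUE)) {
    cfg <- detector_config(random_event_rate = 0,
                           iei_per_event_type = per_type)
    log <- run_detector(rec$data, cfg, dialect = "synthetic")
    acc <- log[log$accepted, , drop = FALSE]
    if (per_type) {
      for (k in unique(acc$kind))
        expect_true(all(diff(acc$time_s[acc$kind == k]) >
                          cfg$inter_event_interval))
    } else {
      expect_true(all(diff(sort(acc$time_s)) > cfg$inter_event_interval))
    }
  }
})

test_that("rejected detections are logged but not accepted", {
  p <- unrest_params(duration_s = 120, rate_hz = 60, seed = 13)
  rec <- generate_unrest(p)
  log <- run_detector(rec$data, detector_config(random_event_rate = 0),
                      dialect = "synthetic")
  ph <- log[log$kind != "random", ]
  expect_gt(nrow(ph), sum(ph$accepted))
  expect_true(all(!is.na(ph$fitted_value)))
})

test_that("the detector is deterministic and handles degenerate streams", {
  expect_identical(nrow(run_detector(data.frame(time_s = numeric(),
                                                pupil = numeric()))), 0L)
  allnan <- data.frame(time_s = (0:599) / 60, pupil = rep(0, 600))
  expect_identical(nrow(run_detector(allnan,
                                     detector_config(random_event_rate = 0))),
                   0L)
  p <- unrest_params(duration_s = 60, rate_hz = 60, seed = 2)
  rec <- generate_unrest(p)
  cfg <- detector_config(rng_seed = 9)
  l1 <- run_detector(rec$data, cfg, dialect = "synthetic")
  l2 <- run_detector(rec$data, cfg, dialect = "synthetic")
  expect_identical(as.data.frame(l1), as.data.frame(l2))
})

test_that("fit windows are NaN-free, bounded, and thresholds update on time", {
  p <- unrest_params(duration_s = 120, rate_hz = 60, seed = 31)
  rec <- generate_unrest(p)
  cfg <- detector_config(random_event_rate = 0)
  log <- run_detector(rec$data, cfg, dialect = "synthetic")
  d <- attr(log, "diagnostics")
  expect_true(all(d$fit_durations <=
                    cfg$max_search_window_duration + 1e-9))
  th <- attr(log, "thresholds")
  expect_true(all(th$valid_fraction >= 0.5))
  # update cadence on a mostly-clean stream is about the baseline duration
  expect_equal(median(diff(th$time_s)), cfg$baseline_window_duration,
               tolerance = 0.05)
  # after any valid update the threshold orderings hold
  expect_true(all(th$constriction_derivative <= th$dilation_derivative))
  expect_true(all(th$trough_size <= th$peak_size))
})

test_that("accepted peaks on a noiseless slow sinusoid align with true maxima", {
  t <- (0:(60 * 60 - 1)) / 60
  y <- 3000 + 100 * sin(2 * pi * 0.5 * t)
  log <- run_detector(data.frame(time_s = t, pupil = y),
                      detector_config(random_event_rate = 0),
                      dialect = "synthetic")
  pk <- log$time_s[log$kind == "peak" & log$accepted]
  expect_gt(length(pk), 0)
  true_max <- 0.5 + 0:29 * 2  # sin(pi * t) peaks where pi * t = pi/2 + 2k*pi
  lag <- vapply(pk, function(tt) min(abs(tt - true_max)), 0)
  expect_true(all(lag <= 0.25))
})
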