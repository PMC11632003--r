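test_that("event accuracy maps times onto the binary index", {
  idx <- integer(100)
  idx[c(10, 20)] <- 1L
  rate <- 1
  expect_equal(event_accuracy(c(9, 19), idx, rate), 100)  # 0-based times
  idx2 <- integer(100)
  idx2[c(10, 20)] <- 1L
  expect_equal(event_accuracy(c(9, 19, 30, 40), idx2, rate), 50)
  expect_identical(event_accuracy(numeric(), idx, rate), NA_real_)
})

test_that("random events score ~50% against a sinusoid's gradient index", {
  t <- (0:(600 * 60 - 1)) / 60
  g <- true_gradient_index(sin(2 * pi * 0.5 * t))
  set.seed(14)
  ev <- stats::runif(2000, 0, 599)
  acc <- event_accuracy(ev, g$dilation_index, 60)
  expect_equal(acc, 50, tolerance = 3)
  # dilation and constriction accuracies are complementary
  acc2 <- event_accuracy(ev, g$constriction_index, 60)
  expect_equal(acc + acc2, 100, tolerance = 0.5)
})

test_that("the sensitivity matrix scores each detected kind per true index", {
  n <- 1000
  truth <- list(dilation_index = integer(n), peak_index = integer(n),
                constriction_index = integer(n), trough_index = integer(n))
  truth$peak_index[100:200] <- 1L
  truth$dilation_index[1:500] <- 1L
  truth$constriction_index[501:1000] <- 1L
  log <- data.frame(
    time_s = c(0.149, 0.151, 0.7),
    kind = c("peak", "peak", "dilation"),
    accepted = TRUE, fitted_value = 1, threshold_snapshot_id = 0L)
  m <- sensitivity_matrix(log, truth, rate_hz = 1000)
  expect_equal(m["peak", "peak"], 100)
  expect_equal(m["peak", "dilation"], 100)
  expect_equal(m["dilation", "constriction"], 100)
  expect_equal(m["dilation", "dilation"], 0)
  expect_true(all(is.na(m["trough", ])))
  expect_true(all(is.na(m["random", ])))
})

test_that("group tests use paired/one-sample t with Holm adjustment", {
  # construct per-subject matrices with known accuracy structure
  mk <- function(on, rnd) {
    m <- matrix(20, 5, 4,
                dimnames = list(c("dilation", "peak", "constriction",
                                  "trough", "random"),
                                c("dilation", "peak", "constriction",
                                  "trough")))
    diag(m[1:4, ]) <- on
    m["random", ] <- rnd
    m
  }
  set.seed(6)
  mats <- lapply(1:8, function(i)
    mk(on = 90 + stats::rnorm(4, 0, 2), rnd = 50 + stats::rnorm(4, 0, 2)))
  res <- accuracy_tests(mats)
  expect_true(all(res$accuracy$p_holm < 0.05))
  expect_true(all(res$accuracy$t > 0))
  expect_true(all(res$sensitivity$p_holm < 0.05))
  # Holm is never smaller than the raw p and preserves the family order
  expect_true(all(res$accuracy$p_holm >= res$accuracy$p))

  # identical accuracy and baseline: t = 0, p = 1 (degenerate branch)
  same <- lapply(1:4, function(i) mk(on = c(50, 50, 50, 50), rnd = 50))
  w0 <- capture_warnings(r0 <- accuracy_tests(same))
  expect_true(all(grepl("zero-variance", w0)))
  expect_true(all(r0$accuracy$t == 0))
  expect_true(all(r0$accuracy$p == 1))

  # constant positive difference: degenerate p of 0
  off <- lapply(1:4, function(i) mk(on = rep(100, 4), rnd = rep(50, 4)))
  w1 <- capture_warnings(r1 <- accuracy_tests(off))
  expect_true(all(grepl("zero-variance", w1)))
  expect_true(all(r1$accuracy$p == 0))
})

test_that("Holm adjustment reproduces the step-down hand computation", {
  mk2 <- function(on) {
    m <- matrix(50, 5, 4,
                dimnames = list(c("dilation", "peak", "constriction",
                                  "trough", "random"),
                                c("dilation", "peak", "constriction",
                                  "trough")))
    diag(m[1:4, ]) <- on
    m
  }
  # choose per-phase differences whose raw p values are strictly ordered,
  # then check the step-down property p_holm = cummax(k_i * p_(i))
  set.seed(8)
  mats <- lapply(1:6, function(i)
    mk2(on = 50 + c(8, 5, 3, 2) + stats::rnorm(4, 0, 3)))
  res <- accuracy_tests(mats)$accuracy
  o <- order(res$p)
  manual <- cummax((4:1) * res$p[o])
  expect_equal(res$p_holm[o], pmin(manual, 1))
})

test_that("temporal performance pools phase events within blocks", {
  log <- data.frame(time_s = c(0, 0.05, 0.15, 1.15, 0.5),
                    kind = c("peak", "dilation", "trough", "peak", "random"),
                    accepted = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                    fitted_value = 1, threshold_snapshot_id = 0L)
  tp <- temporal_performance(log)
  expect_equal(sort(tp$t_prime), c(0.05, 0.10, 1.00))
  expect_equal(tp$group_median_s, 0.10)
  expect_equal(tp$detection_rate_hz, 10)
  expect_equal(sum(tp$histogram$fraction), 1)

  # events at block edges only: every gap spans a block boundary
  blocks <- data.frame(start_s = c(0, 10), end_s = c(5, 15))
  log2 <- data.frame(time_s = c(4.9, 10.1),
                     kind = "peak", accepted = TRUE,
                     fitted_value = 1, threshold_snapshot_id = 0L)
  tp2 <- temporal_performance(log2, blocks)
  expect_length(tp2$t_prime, 0)

  # within-block gaps survive, cross-block gaps are dropped
  log3 <- data.frame(time_s = c(1, 2, 10.5, 11),
                     kind = "peak", accepted = c(TRUE, FALSE, TRUE, TRUE),
                     fitted_value = 1, threshold_snapshot_id = 0L)
  tp3 <- temporal_performance(log3, blocks)
  expect_equal(sort(tp3$t_prime), c(0.5, 1))
})

test_that("the detection rate is the reciprocal of the group median", {
  expect_equal(detection_rate(0.1), 10)
  expect_error(detection_rate(0))
})
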