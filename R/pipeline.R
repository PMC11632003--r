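#' End-to-end accuracy study on a synthetic cohort
#'
#' Emulates the published evaluation design: each subject's pupillary
#' unrest is simulated at the offline acquisition rate (1000 Hz), the
#' detector sees a decimation to the online rate of the preset (~60 Hz for
#' human), and the post hoc ground-truth phase indices (gap interpolation,
#' 0.1 s Savitzky-Golay smoothing, prominence-filtered extrema, gradient
#' signs) are built on the full-rate offline series -- where a 0.1 s
#' smoothing window spans 101 samples and removes measurement noise before
#' extrema are ranked. Detected and random event times are then scored
#' against the offline-rate indices.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Master seed (drives cohort generation and random-event
#'   scheduling).
#' @param params Generator template, an [unrest_params()]; its `rate_hz`
#'   is the offline acquisition rate.
#' @param preset Detector preset (see [species_preset()]); its
#'   `online_rate_hz` is the emulated live rate.
#' @param online_noise_sd Acquisition jitter added to the replayed link
#'   stream, device units (see [replay()]); part of the emulated live
#'   acquisition conditions.
#' @return List: `recordings`, `logs`, `truths`, `matrices` (per-subject
#'   5 x 4), `tests` (from [accuracy_tests()]), `temporal`
#'   (from [temporal_performance()]), `random_gradient_accuracy_pct` (mean
#'   over subjects and the dilation/constriction indices of the
#'   random-event accuracy).
#' @export
cohort_phase_study <- function(n_subjects = 8, seed = 1,
                               params = unrest_params(rate_hz = 1000),
                               preset = species_preset("human"),
                               online_noise_sd = 10) {
  recs <- make_cohort(n_subjects, params, seed = seed)
  logs <- vector("list", n_subjects)
  truths <- vector("list", n_subjects)
  mats <- vector("list", n_subjects)
  rate <- params$rate_hz
  for (i in seq_len(n_subjects)) {
    pre <- preset
    pre$config$rng_seed <- (as.integer(seed) * 131L + i * 17L) %%
      2147483647L
    logs[[i]] <- replay(recs[[i]], pre, offline_rate_hz = rate,
                        online_noise_sd = online_noise_sd)
    pp <- preprocess_pupil(recs[[i]]$data$pupil, rate)
    sm <- smooth_for_truth(pp$values, rate)
    ext <- true_extrema_index(sm, rate)
    grd <- true_gradient_index(sm)
    truths[[i]] <- c(ext, grd, list(blink = pp$blink))
    mats[[i]] <- sensitivity_matrix(logs[[i]], truths[[i]], rate,
                                    t0 = recs[[i]]$data$time_s[1])
  }
  rnd <- vapply(mats, function(m)
    mean(m["random", c("dilation", "constriction")]), 0)
  list(recordings = recs, logs = logs, truths = truths, matrices = mats,
       tests = accuracy_tests(mats),
       temporal = temporal_performance(logs),
       random_gradient_accuracy_pct = mean(rnd))
}
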