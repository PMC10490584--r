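fs <- 250

test_that("reference respiration preprocessing finds inspiration maxima", {
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  resp <- sampled_signal(sin(2 * pi * 0.25 * t), fs)
  out <- preprocess_reference_respiration(resp)
  expect_equal(length(out$peaks$times), 15)
  expect_equal(diff(out$peaks$times), rep(4, 14), tolerance = 0.02)
  # minimum distance contract: >= 1 s apart always
  expect_true(all(diff(out$peaks$times) >= 1))

  # a single huge spike is despiked away: peak set unchanged
  spiked <- resp
  spiked$values[7000] <- 10 * max(resp$values)
  out2 <- preprocess_reference_respiration(spiked)
  expect_equal(out2$peaks$times, out$peaks$times)
})

test_that("R features recover amplitude and interval modulation", {
  rec <- generate_record(synth_config(duration = 120, rsa_depth = 0,
                                      r_amp_mod = 0, q_depth_mod = 0,
                                      seed = 12))
  feats <- extract_r_features(rec$record$signals$ECG)
  # constant HR 60 bpm: intervals all 1.0 s within one sample
  expect_true(all(abs(feats$rr_interval$values - 1.0) <= 1 / fs + 1e-9))
  # constant amplitude: CV below 5%
  cv <- sd(feats$r_amplitude$values) / mean(feats$r_amplitude$values)
  expect_lt(cv, 0.05)
  # anchors respect the 0.64 s minimum distance
  expect_true(all(diff(feats$anchors$times) >= 0.64 - 1e-9))

  # amplitude modulated at 0.25 Hz: the series' dominant frequency
  rec <- generate_record(synth_config(duration = 120, rsa_depth = 0,
                                      r_amp_mod = 0.4, q_depth_mod = 0,
                                      seed = 13))
  feats <- extract_r_features(rec$record$signals$ECG)
  s <- feats$r_amplitude
  grid <- seq(s$times[1], s$times[length(s$times)], by = 0.25)
  y <- spline(s$times, s$values, xout = grid)$y
  spec <- Mod(fft(y - mean(y)))[2:(length(y) %/% 2)]
  f_axis <- (seq_along(spec)) / (length(y) * 0.25)
  expect_lt(abs(f_axis[which.max(spec)] - 0.25), 2 / (length(y) * 0.25))
})

test_that("Q-trough extraction measures the negative-lobe modulation", {
  rec <- generate_record(synth_config(duration = 120, rsa_depth = 0,
                                      r_amp_mod = 0, q_depth_mod = 0.4,
                                      rr_base = 12, seed = 14))
  qs <- extract_q_trough(rec$record$signals$ECG)
  expect_gt(length(qs$times), 100)
  grid <- seq(qs$times[1], qs$times[length(qs$times)], by = 0.25)
  y <- spline(qs$times, qs$values, xout = grid)$y
  spec <- Mod(fft(y - mean(y)))[2:(length(y) %/% 2)]
  f_axis <- (seq_along(spec)) / (length(y) * 0.25)
  expect_lt(abs(f_axis[which.max(spec)] - 0.2), 2 / (length(y) * 0.25))

  # signal that is all-positive after band-passing: no rectified content
  t <- seq(0, 30, by = 1 / fs)
  pos <- sampled_signal(rep(0, length(t)), fs)
  expect_error(extract_q_trough(pos),
               class = "cardioresp_estimation_failure")
})

test_that("300% rule removes outliers then normalizes to unit magnitude", {
  s <- modulation_series(1:4, c(1, 1, 1, 10), "r_amplitude")
  out <- clean_and_normalize(s)
  # mean |v| = 3.25, threshold 9.75: the 10 goes; survivors / 3.25
  expect_equal(out$times, 1:3)
  expect_equal(out$values, c(1, 1, 1) / 3.25)

  const <- modulation_series(1:5, rep(4, 5), "r_amplitude")
  out <- clean_and_normalize(const)
  expect_equal(out$values, rep(1, 5))

  inb <- modulation_series(1:6, c(0.8, 1.2, 0.9, 1.1, 1.0, 1.0),
                           "rr_interval")
  out <- clean_and_normalize(inb)
  expect_equal(length(out$values), 6)
  expect_equal(mean(abs(out$values)), 1, tolerance = 1e-12)

  expect_error(clean_and_normalize(modulation_series(1:2, c(1, 2),
                                                     "q_trough")),
               class = "cardioresp_invalid_parameter")
})

test_that("composite assembly averages spline-resampled components", {
  # three identical sinusoidal series reproduce the band-passed sinusoid
  tt <- seq(0, 120, by = 0.9)
  v <- sin(2 * pi * 0.25 * tt)
  mk <- function(kind) modulation_series(tt, v, kind)
  comp <- build_composite(mk("r_amplitude"), mk("rr_interval"),
                          mk("q_trough"), fs = 50)
  truth <- sin(2 * pi * 0.25 * signal_times(comp$composite))
  mid <- seq(500, length(truth) - 500)
  expect_gt(cor(comp$composite$values[mid], truth[mid]), 0.99)

  # averaging three noisy copies beats any single noisy component
  set.seed(31)
  mk_noisy <- function(kind) modulation_series(tt, v + rnorm(length(tt), 0, 0.5), kind)
  s1 <- mk_noisy("r_amplitude"); s2 <- mk_noisy("rr_interval")
  s3 <- mk_noisy("q_trough")
  comp3 <- build_composite(s1, s2, s3, fs = 50)
  comp1 <- build_composite(s1, s1, s1, fs = 50)
  truth3 <- sin(2 * pi * 0.25 * signal_times(comp3$composite))
  err3 <- comp3$composite$values - truth3 *
    sd(comp3$composite$values) / sd(truth3)
  err1 <- comp1$composite$values - truth3 *
    sd(comp1$composite$values) / sd(truth3)
  expect_lt(cor(comp1$composite$values, truth3),
            cor(comp3$composite$values, truth3))

  # non-overlapping spans fail loudly
  a <- modulation_series(seq(0, 20, 0.9), rnorm(23), "r_amplitude")
  b <- modulation_series(seq(100, 120, 0.9), rnorm(23), "rr_interval")
  expect_error(build_composite(a, b, a, fs = 50),
               class = "cardioresp_estimation_failure")
})

test_that("spline resampling reconstructs band-limited beat-wise samples", {
  # breath-band signal sampled at beat rate >= 4x its frequency
  set.seed(6)
  beat_t <- cumsum(runif(150, 0.85, 1.15))
  f <- 0.25
  v <- sin(2 * pi * f * beat_t) + 0.4 * sin(2 * pi * 0.15 * beat_t + 0.7)
  grid <- seq(beat_t[5], beat_t[145], by = 1 / 50)
  rec <- spline(beat_t, v, xout = grid, method = "fmm")$y
  truth <- sin(2 * pi * f * grid) + 0.4 * sin(2 * pi * 0.15 * grid + 0.7)
  expect_lt(sqrt(mean((rec - truth)^2)) / sqrt(mean(truth^2)), 0.05)
})

test_that("phase alignment recovers a global shift and labels accuracy", {
  set.seed(41)
  ref_t <- seq(2, 118, by = 4)
  ref <- event_series(ref_t, "breath", "reference")
  mk_comp <- function(det_t) {
    structure(list(
      composite = sampled_signal(rep(0, 120 * 50), 50),
      components = list(),
      breath_peaks = event_series(det_t, "breath", "detected"),
      phase_shift = 0), class = "composite_edr")
  }
  # exact match: all TP, shift 0
  out <- align_and_score_breaths(mk_comp(ref_t), ref, beat_interval = 1.0)
  expect_equal(out$report$phase_shift, 0)
  expect_equal(out$report$tp, length(ref_t))
  expect_equal(out$report$fp + out$report$fn, 0)

  # detected lag the reference by 0.4 s: recovered by the 0.2 s-bin search
  out <- align_and_score_breaths(mk_comp(ref_t - 0.4), ref,
                                 beat_interval = 1.0)
  expect_equal(out$report$phase_shift, 0.4)
  expect_equal(out$report$tp, length(ref_t))

  # a peak 0.7 beat intervals away is "inaccurate", not TP or FP
  det <- ref_t
  det[3] <- ref_t[3] + 0.7
  out <- align_and_score_breaths(mk_comp(det), ref, beat_interval = 1.0)
  expect_equal(out$report$inaccurate, 1)
  expect_equal(out$report$tp, length(ref_t) - 1)
  expect_equal(out$report$fn, 1)
})

test_that("full EDR pipeline reconstructs synthetic respiration", {
  rec <- generate_record(synth_config(duration = 300, seed = 23))
  fit <- edr(rec$record$signals$ECG, rec$record$signals$RESP)

  # breath peaks within half a beat of truth for >= 90% of breaths
  expect_gte(fit$report$sensitivity, 0.90)

  # composite is band-limited to the respiration band
  v <- fit$composite$composite$values
  sp <- Mod(fft(v - mean(v)))^2
  f_axis <- (seq_along(sp) - 1) / length(sp) * fs
  half <- f_axis <= fs / 2
  inband <- half & f_axis >= 0.10 & f_axis <= 0.55
  expect_lt(sum(sp[half & !inband]) / sum(sp[half]), 0.10)

  # windowed respiration-rate agreement with truth
  span <- c(30, 270)
  # truth RR is exactly constant, so NRMSE is undefined (warns); only the
  # MAE is of interest here
  m <- suppressWarnings(
    compute_metrics(window_rates(rec$breaths, span),
                    window_rates(fit$composite$breath_peaks, span)))
  expect_lte(m$mae, 1)
})

test_that("EDR is invariant to a common rescaling of the input ECG", {
  rec <- generate_record(synth_config(duration = 120, seed = 25))
  f1 <- edr(rec$record$signals$ECG)
  ecg10 <- sampled_signal(rec$record$signals$ECG$values * 10, fs)
  f2 <- edr(ecg10)
  expect_equal(f2$composite$breath_peaks$times,
               f1$composite$breath_peaks$times, tolerance = 1 / fs)
  expect_equal(f2$composite$composite$values, f1$composite$composite$values,
               tolerance = 1e-6)
})
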