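test_that("beat classification applies the 140/320 ms window rules", {
  ref <- event_series(c(10), "beat", "reference")
  det <- event_series(c(10.1), "beat", "detected")
  rep <- classify_beats(det, ref)
  expect_equal(rep$labels, "TP")
  expect_equal(c(rep$tp, rep$fp, rep$fn), c(1, 0, 0))

  # 300 ms after the annotation: T-wave misdetection, annotation missed
  det <- event_series(c(10.3), "beat", "detected")
  rep <- classify_beats(det, ref)
  expect_equal(rep$labels, "T_wave")
  expect_equal(c(rep$tp, rep$t_wave, rep$fn), c(0, 1, 1))

  # perfect detection
  ref <- event_series(seq(1, 60), "beat", "reference")
  rep <- classify_beats(ref, ref)
  expect_equal(rep$precision, 1)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$fn, 0)

  expect_warning(classify_beats(det, event_series(numeric(0), "beat",
                                                  "reference")),
                 "sensitivity")
})

test_that("beat classification matches the exhaustive matcher on random sets", {
  set.seed(101)
  for (i in 1:60) {
    ref <- sort(runif(sample(3:25, 1), 0, 30))
    # jittered copy of most references plus a few spurious detections
    keep <- runif(length(ref)) < 0.85
    det <- sort(unique(c(ref[keep] + rnorm(sum(keep), 0, 0.12),
                         runif(sample(0:6, 1), 0, 30))))
    det <- det[det >= 0]
    if (length(det) < 1) next
    got <- classify_beats(event_series(det, "beat", "detected"),
                          event_series(ref, "beat", "reference"))
    want <- oracle_classify(det, ref)
    expect_equal(got$tp, want$tp, info = paste("case", i))
    expect_equal(got$fp, want$fp, info = paste("case", i))
    expect_equal(got$t_wave, want$t_wave, info = paste("case", i))
    expect_equal(got$fn, want$fn, info = paste("case", i))
    # two-sided bookkeeping: detected-side TP equals reference-side TP
    expect_equal(got$tp + got$fn, length(ref))
    expect_equal(got$tp + got$fp + got$t_wave, length(det))
  }
})

test_that("windowed rates count events per minute over stepping windows", {
  ev <- event_series(seq(0.5, 299.5, by = 1), "beat", "detected")
  rs <- window_rates(ev, c(0, 300))
  expect_equal(rs$window_starts, seq(0, 240, by = 10))
  expect_true(all(rs$rates == 60))

  empty <- event_series(numeric(0), "beat", "detected")
  expect_true(all(window_rates(empty, c(0, 300))$rates == 0))

  set.seed(8)
  pois <- event_series(cumsum(rexp(400, rate = 1.2)), "beat", "detected")
  rs <- window_rates(pois, c(0, 300))
  expect_lt(abs(mean(rs$rates) - 72), 6)

  expect_warning(window_rates(ev, c(0, 30)), "truncated")
})

test_that("agreement metrics match the straight-from-formula oracle", {
  r <- c(60, 62, 65, 64, 61)
  same <- compute_metrics(r, r)
  expect_equal(same$mae, 0)
  expect_equal(same$pe, 0)
  expect_equal(same$nrmse, 0)
  expect_equal(same$rho_p, 1)
  expect_equal(same$rho_c, 1)

  off <- compute_metrics(r, r + 3)
  expect_equal(off$mae, 3)
  expect_equal(off$rho_p, 1)
  expect_lt(off$rho_c, 1)

  set.seed(55)
  for (i in 1:50) {
    r <- runif(50, 50, 90)
    c_ <- r + rnorm(50, 0, 5)
    got <- compute_metrics(r, c_)
    want <- oracle_metrics(r, c_)
    for (k in c("mae", "pe", "nrmse", "rho_p", "p_value", "rho_c"))
      expect_equal(got[[k]], want[[k]], tolerance = 1e-10,
                   info = paste(k, "case", i))
    expect_lte(abs(got$rho_c), abs(got$rho_p) + 1e-9)
  }

  expect_warning(compute_metrics(rep(60, 5), c(60, 61, 60, 61, 60)),
                 "constant")
  expect_error(compute_metrics(1, 1), class = "cardioresp_invalid_parameter")
})

test_that("the printed Pearson variant is exposed but not the default", {
  r <- c(60, 64, 68, 62, 66)
  c_ <- c(61, 63, 70, 60, 67)
  std <- compute_metrics(r, c_)
  expect_equal(std$rho_p, cor(r, c_))
  printed <- compute_metrics(r, c_, pearson = "printed")
  expect_false(isTRUE(all.equal(printed$rho_p, cor(r, c_))))
})

test_that("best-fit alignment recovers a global event shift", {
  set.seed(2)
  ref_t <- cumsum(runif(260, 0.8, 1.2))
  ref <- event_series(ref_t, "beat", "reference")
  span <- c(0, max(ref_t))

  calc <- event_series(ref_t + 2.0, "beat", "detected")
  aligned <- best_fit_align(ref, calc, span)
  expect_equal(attr(aligned, "shift"), -2.0, tolerance = 0.11)
  expect_lt(attr(aligned, "mae"), 0.5)

  aligned0 <- best_fit_align(ref, ref, span)
  expect_equal(attr(aligned0, "shift"), 0)

  # alignment never increases the windowed MAE
  jit <- event_series(ref_t + 0.7, "beat", "detected")
  unshifted_mae <- mean(abs(window_rates(ref, span)$rates -
                              window_rates(jit, span)$rates))
  expect_lte(attr(best_fit_align(ref, jit, span), "mae"), unshifted_mae)

  # shift beyond the +/-3 s search: residual error persists
  far <- event_series(ref_t + 5.0, "beat", "detected")
  expect_gt(attr(best_fit_align(ref, far, span), "mae"), 0)
})

test_that("sectioned waveform correlation absorbs lags within +/-3 s", {
  fs <- 250
  t <- seq(0, 160, by = 1 / fs)
  base <- sin(2 * pi * 0.25 * t) + 0.3 * sin(2 * pi * 0.4 * t + 1)
  ref <- sampled_signal(base, fs)
  expect_equal(waveform_correlation(ref, ref)$mean_correlation, 1,
               tolerance = 1e-9)

  delayed <- sampled_signal(sin(2 * pi * 0.25 * (t - 1)) +
                              0.3 * sin(2 * pi * 0.4 * (t - 1) + 1), fs)
  wc <- waveform_correlation(ref, delayed)
  # the final section cannot look 1 s past the end of the record, so judge
  # the sections with full lag coverage
  full <- seq_len(length(wc$per_section) - 1)
  expect_gt(mean(wc$per_section[full]), 0.99)
  expect_equal(median(wc$best_lags), 1, tolerance = 0.05)

  set.seed(4)
  # independent band-limited noise: far below the matched-signal regime
  # (the max-over-lags search inflates the null, so not strictly near zero)
  other <- bandpass(sampled_signal(rnorm(length(t)), fs), 0.15, 0.5)
  expect_lt(waveform_correlation(ref, other)$mean_correlation, 0.5)

  expect_error(waveform_correlation(ref, sampled_signal(base, 100)),
               class = "cardioresp_invalid_parameter")
})
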