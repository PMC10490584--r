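#' Configuration for the ECG-derived respiration pipeline
#'
#' All stage parameters of [edr()] with their defaults. Frame lengths are
#' given in seconds; at the native 250 Hz sampling rate the defaults
#' correspond to frames of 75 samples (0.3 s), 300 samples (1.2 s) and
#' minimum peak distances of 160 samples (0.64 s) and 250 samples (1 s).
#'
#' @param resp_band Respiration band, Hz (reference preprocessing and final
#'   composite).
#' @param resp_min_prominence_frac Breath-peak prominence threshold as a
#'   fraction of the waveform maximum.
#' @param resp_min_distance_s Minimum breath-peak separation, s.
#' @param outlier_k Outlier despiking threshold in units of MAD from the
#'   median; flagged samples are replaced by the previous retained sample.
#' @param r_band Band for the R-peak processing chain, Hz.
#' @param r_mm_frame_s Moving-mean frame for the squared ECG, s (applied
#'   twice).
#' @param r_min_distance_s Minimum R-anchor separation, s.
#' @param r_min_prominence_frac R-peak prominence threshold as a fraction of
#'   the processed maximum.
#' @param q_band Band for the Q-trough chain, Hz.
#' @param q_mm_frame_s Moving-mean frame for the rectified ECG, s (applied
#'   three times).
#' @param q_min_distance_s Minimum Q-anchor separation, s.
#' @param q_min_height_frac Q-trough height threshold as a fraction of the
#'   processed maximum.
#' @param clean_k Beat-feature outlier rule: points with `|value|` beyond
#'   `clean_k` times the mean absolute value are removed (the 300% rule).
#' @param clean_on Apply the rule to raw absolute values (`"value"`) or to
#'   deviations from the series mean (`"deviation"`).
#' @param average_mode `"mean"` divides the summed components by 3 before
#'   the moving mean; `"sum"` relies on the moving mean alone.
#' @param composite_mm_frame_s Moving-mean frame for the composite, s.
#' @param max_phase_shift_s Maximum phase-alignment shift, s.
#' @param phase_step_s Phase-alignment bin width, s.
#' @return A list of class `edr_config`.
#' @export
edr_config <- function(resp_band = c(0.15, 0.5),
                       resp_min_prominence_frac = 0.025,
                       resp_min_distance_s = 1.0,
                       outlier_k = 8,
                       r_band = c(1, 25),
                       r_mm_frame_s = 0.3,
                       r_min_distance_s = 0.64,
                       r_min_prominence_frac = 0.005,
                       q_band = c(0.1, 25),
                       q_mm_frame_s = 0.3,
                       q_min_distance_s = 0.64,
                       q_min_height_frac = 0.10,
                       clean_k = 3,
                       clean_on = c("value", "deviation"),
                       average_mode = c("mean", "sum"),
                       composite_mm_frame_s = 1.2,
                       max_phase_shift_s = 1.4,
                       phase_step_s = 0.2) {
  cfg <- as.list(environment())
  cfg$clean_on <- match.arg(clean_on)
  cfg$average_mode <- match.arg(average_mode)
  class(cfg) <- "edr_config"
  cfg
}

# replace samples > k MADs from the median by the previous retained sample
replace_outliers <- function(v, k) {
  med <- stats::median(v)
  s <- stats::mad(v)
  if (s == 0) return(v)
  bad <- abs(v - med) > k * s
  if (!any(bad)) return(v)
  idx <- seq_along(v)
  src <- cummax(ifelse(bad, 0L, idx))
  first_ok <- which(!bad)[1]
  src[src == 0L] <- first_ok
  v[src]
}

#' Preprocess the reference respiration channel
#'
#' Despikes, band-passes to the respiration band and locates the reference
#' inspiration maxima used to score the reconstructed waveform.
#'
#' @param resp A [sampled_signal()] respiration trace.
#' @param config An [edr_config()].
#' @return A list with `signal` (filtered `sampled_signal`) and `peaks`
#'   (reference breath [event_series()]).
#' @export
preprocess_reference_respiration <- function(resp, config = edr_config()) {
  resp <- as_sampled_signal(resp)
  v <- replace_outliers(resp$values, config$outlier_k)
  y <- bandpass(sampled_signal(v, resp$fs, resp$t0),
                config$resp_band[1], config$resp_band[2])
  pk <- find_peaks(y,
                   min_distance = round(config$resp_min_distance_s * y$fs),
                   min_prominence = config$resp_min_prominence_frac *
                     max(y$values))
  if (!length(pk$indices))
    stop_estimation("no inspiration peaks found in the reference respiration")
  list(signal = y,
       peaks = event_series(peak_times(pk), label = "breath",
                            source = "reference"))
}

#' Extract R-peak amplitude and R-R interval modulation series
#'
#' Band-passes the ECG to 1-25 Hz, squares it, smooths twice with a moving
#' mean, and locates the R anchors. Peak heights give the amplitude
#' modulation; consecutive anchor spacings (assigned to the interval
#' midpoint) give the frequency modulation of the sinus rhythm.
#'
#' @param ecg A [sampled_signal()] single-lead ECG.
#' @param config An [edr_config()].
#' @return A list with `r_amplitude` and `rr_interval`
#'   [modulation_series()], plus `anchors` (the R anchor [event_series()]).
#' @export
extract_r_features <- function(ecg, config = edr_config()) {
  ecg <- as_sampled_signal(ecg)
  if (ecg$fs < 60)
    stop_invalid("sampling rate %g Hz too low for the %g Hz band edge",
                 ecg$fs, config$r_band[2])
  y <- bandpass(ecg, config$r_band[1], config$r_band[2])
  y <- sampled_signal(y$values^2, y$fs, y$t0)
  frame <- round(config$r_mm_frame_s * ecg$fs)
  y <- moving_mean(moving_mean(y, frame), frame)
  pk <- find_peaks(y,
                   min_distance = round(config$r_min_distance_s * y$fs),
                   min_prominence = config$r_min_prominence_frac *
                     max(y$values))
  if (length(pk$indices) < 3L)
    stop_estimation("fewer than 3 R peaks found; cannot derive modulation series")
  tt <- peak_times(pk)
  rr <- diff(tt)
  list(r_amplitude = modulation_series(tt, pk$heights, "r_amplitude"),
       rr_interval = modulation_series((tt[-1] + tt[-length(tt)]) / 2, rr,
                                       "rr_interval"),
       anchors = event_series(tt, label = "beat", source = "detected"))
}

#' Extract the Q-trough depth modulation series
#'
#' Band-passes the ECG to 0.1-25 Hz, keeps only the negative excursions and
#' inverts them, smooths three times with a moving mean, and measures the
#' trough-depth peaks.
#'
#' @param ecg A [sampled_signal()] single-lead ECG.
#' @param config An [edr_config()].
#' @return A `q_trough` [modulation_series()].
#' @export
extract_q_trough <- function(ecg, config = edr_config()) {
  ecg <- as_sampled_signal(ecg)
  y <- bandpass(ecg, config$q_band[1], config$q_band[2])
  neg <- -pmin(y$values, 0)
  if (all(neg == 0))
    stop_estimation("no negative excursions after band-passing; cannot measure Q troughs")
  z <- sampled_signal(neg, y$fs, y$t0)
  frame <- round(config$q_mm_frame_s * ecg$fs)
  for (i in 1:3) z <- moving_mean(z, frame)
  pk <- find_peaks(z,
                   min_distance = round(config$q_min_distance_s * z$fs),
                   min_height = config$q_min_height_frac * max(z$values))
  if (length(pk$indices) < 3L)
    stop_estimation("fewer than 3 Q troughs found")
  modulation_series(peak_times(pk), pk$heights, "q_trough")
}

#' Remove beat-feature outliers and normalize to unit mean magnitude
#'
#' Applies the 300% rule: with `m = mean(|values|)` computed once, points
#' with `|value| > clean_k * m` are removed, and the survivors are divided
#' by `m` so the series becomes unitless with mean magnitude near 1.
#'
#' @param series A [modulation_series()] with at least 3 points.
#' @param config An [edr_config()] (supplies `clean_k` and `clean_on`).
#' @return The cleaned, normalized `modulation_series`.
#' @export
clean_and_normalize <- function(series, config = edr_config()) {
  stopifnot(inherits(series, "modulation_series"))
  if (length(series$values) < 3L)
    stop_invalid("need at least 3 points to clean a modulation series")
  v <- series$values
  dev <- if (config$clean_on == "deviation") v - mean(v) else v
  m <- mean(abs(dev))
  keep <- if (m == 0) rep(TRUE, length(v)) else abs(dev) <= config$clean_k * m
  if (!any(keep))
    stop_estimation("all points removed by the %g00%% outlier rule",
                    config$clean_k)
  norm <- mean(abs(v))
  if (norm == 0) norm <- 1
  modulation_series(series$times[keep], v[keep] / norm, series$kind)
}

#' Assemble the composite ECG-derived respiration waveform
#'
#' Cubic-spline resamples the three cleaned modulation series onto a common
#' uniform grid spanning their overlap, averages them, smooths with a moving
#' mean and band-passes to the respiration band, then locates the
#' inspiration peaks of the reconstruction.
#'
#' @param r_amp,rr_int,q_trough Cleaned [modulation_series()] objects.
#' @param fs Output sampling rate, Hz.
#' @param config An [edr_config()].
#' @return An object of class `composite_edr`: `composite`
#'   ([sampled_signal()]), `components` (list of the three resampled
#'   signals), `breath_peaks` ([event_series()]), `phase_shift` (s, 0 until
#'   [align_and_score_breaths()] is applied).
#' @export
build_composite <- function(r_amp, rr_int, q_trough, fs,
                            config = edr_config()) {
  series <- list(r_amp, rr_int, q_trough)
  for (s in series) stopifnot(inherits(s, "modulation_series"))
  spans <- vapply(series, function(s) diff(range(s$times)), numeric(1))
  if (any(spans < 10))
    stop_invalid("each modulation series must span at least 10 s (got %.1f s)",
                 min(spans))
  t_start <- max(vapply(series, function(s) s$times[1], numeric(1)))
  t_end <- min(vapply(series, function(s) s$times[length(s$times)],
                      numeric(1)))
  if (t_end - t_start < 10)
    stop_estimation("modulation series overlap (%.1f s) too short",
                    t_end - t_start)
  grid <- seq(t_start, t_end, by = 1 / fs)
  comp_list <- lapply(series, function(s) {
    sampled_signal(stats::spline(s$times, s$values, xout = grid,
                                 method = "fmm")$y, fs, t_start)
  })
  total <- comp_list[[1]]$values + comp_list[[2]]$values +
    comp_list[[3]]$values
  if (config$average_mode == "mean") total <- total / 3
  y <- moving_mean(sampled_signal(total, fs, t_start),
                   round(config$composite_mm_frame_s * fs))
  y <- bandpass(y, config$resp_band[1], config$resp_band[2])
  pk <- find_peaks(y,
                   min_distance = round(config$resp_min_distance_s * fs),
                   min_prominence = config$resp_min_prominence_frac *
                     max(y$values))
  names(comp_list) <- c("r_amplitude", "rr_interval", "q_trough")
  structure(list(composite = y,
                 components = comp_list,
                 breath_peaks = event_series(peak_times(pk),
                                             label = "breath",
                                             source = "detected"),
                 phase_shift = 0),
            class = "composite_edr")
}

#' @export
print.composite_edr <- function(x, ...) {
  cat(sprintf("<composite_edr> %d breath peaks over %.1f s, phase shift %.1f s\n",
              length(x$breath_peaks$times),
              length(x$composite$values) / x$composite$fs, x$phase_shift))
  invisible(x)
}

#' Phase-align the composite to the reference and score breath detections
#'
#' Evaluates candidate shifts on a 0.2 s grid up to 1.4 s, applies the shift
#' minimizing the mean absolute distance from each composite peak to its
#' nearest reference peak, then labels each shifted peak: true positive if
#' within half an average heartbeat of an unmatched reference peak,
#' "inaccurate" if within 50-100% of a heartbeat, otherwise false positive;
#' unmatched reference peaks count as false negatives.
#'
#' @param composite A `composite_edr` from [build_composite()].
#' @param reference_peaks Reference breath [event_series()] (>= 3 peaks).
#' @param beat_interval Average heartbeat period in seconds (the half-beat
#'   scoring unit).
#' @param config An [edr_config()].
#' @return A list with `composite` (phase-shifted copy) and `report` (a
#'   `breath_report`: labels, counts, `precision`, `sensitivity`,
#'   `annotations_pct`, `phase_shift`).
#' @export
align_and_score_breaths <- function(composite, reference_peaks,
                                    beat_interval,
                                    config = edr_config()) {
  stopifnot(inherits(composite, "composite_edr"),
            inherits(reference_peaks, "event_series"))
  ref <- reference_peaks$times
  if (length(ref) < 3L)
    stop_invalid("need at least 3 reference peaks to align and score")
  det0 <- composite$breath_peaks$times
  shifts <- seq(0, config$max_phase_shift_s, by = config$phase_step_s)
  cost <- vapply(shifts, function(s) {
    if (!length(det0)) return(Inf)
    mean(vapply(det0 + s, function(d) min(abs(d - ref)), numeric(1)))
  }, numeric(1))
  best <- shifts[which.min(cost)]
  det <- det0 + best

  half <- 0.5 * beat_interval
  m <- greedy_match(det, ref, half)
  labels <- rep("FP", length(det))
  labels[m$det_idx] <- "TP"
  unmatched_ref <- setdiff(seq_along(ref), m$ref_idx)
  for (i in which(labels == "FP")) {
    d <- min(abs(det[i] - ref))
    if (d > half && d <= beat_interval) labels[i] <- "inaccurate"
  }
  tp <- sum(labels == "TP"); fp <- sum(labels == "FP")
  inac <- sum(labels == "inaccurate")
  fn <- length(unmatched_ref)
  report <- structure(list(
    labels = labels, tp = tp, fp = fp, fn = fn, inaccurate = inac,
    n_detected = length(det), n_reference = length(ref),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    annotations_pct = 100 * length(det) / length(ref),
    phase_shift = best), class = "breath_report")
  shifted <- composite
  shifted$breath_peaks <- event_series(det, label = "breath",
                                       source = "detected")
  shifted$composite$t0 <- shifted$composite$t0 + best
  shifted$phase_shift <- best
  list(composite = shifted, report = report)
}

#' @export
print.breath_report <- function(x, ...) {
  cat("Breath detection vs. reference inspiration maxima\n")
  cat(sprintf("  TP %d  FP %d  FN %d  inaccurate %d  (shift %.1f s)\n",
              x$tp, x$fp, x$fn, x$inaccurate, x$phase_shift))
  cat(sprintf("  precision %.1f%%  sensitivity %.1f%%  annotations %.1f%%\n",
              100 * x$precision, 100 * x$sensitivity, x$annotations_pct))
  invisible(x)
}

# greedy nearest-first matching: repeatedly take the globally closest
# (detected, reference) pair within `window`, each side used once.
greedy_match <- function(det, ref, window) {
  if (!length(det) || !length(ref))
    return(list(det_idx = integer(0), ref_idx = integer(0)))
  d <- abs(outer(det, ref, "-"))
  d[d > window] <- Inf
  det_idx <- integer(0); ref_idx <- integer(0)
  while (any(is.finite(d))) {
    k <- which.min(d)   # ties: smallest linear index = earliest det then ref
    i <- (k - 1L) %% length(det) + 1L
    j <- (k - 1L) %/% length(det) + 1L
    det_idx <- c(det_idx, i); ref_idx <- c(ref_idx, j)
    d[i, ] <- Inf; d[, j] <- Inf
  }
  list(det_idx = det_idx, ref_idx = ref_idx)
}

#' ECG-derived respiration: reconstruct a respiration waveform from ECG
#'
#' Runs the full composite-EDR pipeline: extracts the R-peak amplitude, R-R
#' interval and Q-trough depth modulation series from a single-lead ECG,
#' cleans and normalizes each, spline-resamples them onto a common grid and
#' averages them into a band-limited composite respiration waveform. When a
#' reference respiration channel is supplied, the composite is phase-aligned
#' to it and its inspiration peaks are scored.
#'
#' @param ecg A [sampled_signal()] single-lead ECG, or a numeric vector with
#'   `fs`.
#' @param resp Optional [sampled_signal()] reference respiration channel.
#' @param fs Sampling rate when `ecg` is a plain vector.
#' @param config An [edr_config()].
#' @return An object of class `edr`: `composite` (`composite_edr`),
#'   `series` (cleaned modulation series), `beat_interval` (mean R-R, s),
#'   `reference` (preprocessed reference or `NULL`), `report`
#'   (`breath_report` or `NULL`), `config`.
#' @examples
#' rec <- generate_record(synth_config(duration = 120, seed = 1))
#' fit <- edr(rec$record$signals$ECG, rec$record$signals$RESP)
#' fit
#' @export
edr <- function(ecg, resp = NULL, fs = NULL, config = edr_config()) {
  if (is.numeric(ecg) && !inherits(ecg, "sampled_signal")) {
    if (is.null(fs)) stop_invalid("supply 'fs' when 'ecg' is a plain vector")
    ecg <- sampled_signal(ecg, fs)
  }
  ecg <- as_sampled_signal(ecg)
  rfeat <- extract_r_features(ecg, config)
  qser <- extract_q_trough(ecg, config)
  beat_interval <- mean(rfeat$rr_interval$values)
  cleaned <- list(
    r_amplitude = clean_and_normalize(rfeat$r_amplitude, config),
    rr_interval = clean_and_normalize(rfeat$rr_interval, config),
    q_trough = clean_and_normalize(qser, config))
  comp <- build_composite(cleaned$r_amplitude, cleaned$rr_interval,
                          cleaned$q_trough, fs = ecg$fs, config = config)
  reference <- NULL
  report <- NULL
  if (!is.null(resp)) {
    reference <- preprocess_reference_respiration(as_sampled_signal(resp),
                                                  config)
    scored <- align_and_score_breaths(comp, reference$peaks, beat_interval,
                                      config)
    comp <- scored$composite
    report <- scored$report
  }
  structure(list(composite = comp, series = cleaned,
                 beat_interval = beat_interval, reference = reference,
                 report = report, config = config, call = match.call()),
            class = "edr")
}

#' @export
print.edr <- function(x, ...) {
  cat("ECG-derived respiration (composite of R amplitude, R-R, Q trough)\n")
  cat(sprintf("  mean heartbeat period %.3f s\n", x$beat_interval))
  print(x$composite)
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' @export
summary.edr <- function(object, ...) {
  br <- diff(object$composite$breath_peaks$times)
  out <- list(
    n_breaths = length(object$composite$breath_peaks$times),
    mean_rr_bpm = if (length(br)) 60 / mean(br) else NA_real_,
    beat_interval_s = object$beat_interval,
    phase_shift_s = object$composite$phase_shift,
    report = object$report)
  class(out) <- "summary.edr"
  out
}

#' @export
print.summary.edr <- function(x, ...) {
  cat("ECG-derived respiration\n")
  cat(sprintf("  %d breaths, mean respiration rate %.1f breaths/min\n",
              x$n_breaths, x$mean_rr_bpm))
  cat(sprintf("  mean heartbeat period %.3f s, phase shift %.1f s\n",
              x$beat_interval_s, x$phase_shift_s))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' @export
fitted.edr <- function(object, ...) object$composite$composite

#' @export
plot.edr <- function(x, ...) {
  comp <- x$composite$composite
  plot(comp, main = "Composite ECG-derived respiration", ...)
  if (!is.null(x$reference)) {
    ref <- x$reference$signal
    sc <- stats::sd(comp$values) / max(stats::sd(ref$values), 1e-12)
    graphics::lines(signal_times(ref), ref$values * sc, col = "grey60")
    graphics::legend("topright", legend = c("composite", "reference (scaled)"),
                     col = c("black", "grey60"), lty = 1, bty = "n")
  }
  graphics::points(x$composite$breath_peaks$times,
                   rep(max(comp$values), length(x$composite$breath_peaks$times)),
                   pch = 25, col = "tomato", bg = "tomato", cex = 0.6)
  invisible(x)
}
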