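#' Configuration for the synthetic coupled ECG + respiration generator
#'
#' Defaults describe a healthy supine adult at 250 Hz: heart rate 60 bpm,
#' respiration 15 breaths/min (4 beats per breath), modest respiratory sinus
#' arrhythmia, respiration-coupled R-amplitude and Q-depth modulation, and a
#' cardiogenic ripple in the respiration channel five times the white-noise
#' floor, delayed 120 ms after the electrical beat (the mechanical
#' propagation delay the heartbeat detector corrects for).
#'
#' @param fs Sampling rate, Hz.
#' @param duration Record length, s.
#' @param hr_base Baseline heart rate, bpm.
#' @param rr_base Respiration rate, breaths/min.
#' @param rsa_depth Fractional modulation of the instantaneous heart rate by
#'   respiration phase (respiratory sinus arrhythmia).
#' @param r_amp_mod Fractional respiration-phase modulation of the R-peak
#'   amplitude.
#' @param q_depth_mod Fractional respiration-phase modulation of the Q and S
#'   trough depths.
#' @param cardio_coupling Peak amplitude of the cardiogenic ripple in the
#'   respiration channel, in units of the (unit) tidal amplitude.
#' @param cardio_delay Delay of the mechanical ripple after the R wave, s.
#' @param noise_sd White-noise SD on the respiration channel (tidal
#'   amplitude units).
#' @param ecg_noise_sd White-noise SD on the ECG channel (R-amplitude
#'   units).
#' @param powerline_hz Powerline frequency (50, 60) or `NA` for none.
#' @param powerline_amp Powerline interference amplitude.
#' @param baseline_wander_amp Amplitude of slow (0.05 Hz) baseline wander on
#'   the respiration channel.
#' @param seed Integer seed; fully determines the record.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 250,
                         duration = 300,
                         hr_base = 60,
                         rr_base = 15,
                         rsa_depth = 0.08,
                         r_amp_mod = 0.30,
                         q_depth_mod = 0.30,
                         cardio_coupling = 0.05,
                         cardio_delay = 0.120,
                         noise_sd = 0.01,
                         ecg_noise_sd = 0.02,
                         powerline_hz = 50,
                         powerline_amp = 0.005,
                         baseline_wander_amp = 0.10,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$fs <= 0 || cfg$duration <= 0 || cfg$hr_base <= 0 ||
      cfg$rr_base <= 0)
    stop_invalid("fs, duration, hr_base and rr_base must all be positive")
  if (cfg$noise_sd < 0 || cfg$ecg_noise_sd < 0)
    stop_invalid("noise SDs must be non-negative")
  class(cfg) <- "synth_config"
  cfg
}

# PQRST template: five Gaussians (offset s, amplitude, width s) relative to
# the R wave; amplitudes in units of the nominal R height.
pqrst_template <- function() {
  list(P = c(-0.200, 0.15, 0.025),
       Q = c(-0.035, -0.12, 0.010),
       R = c(0.000, 1.00, 0.012),
       S = c(0.035, -0.18, 0.010),
       T = c(0.250, 0.35, 0.045))
}

#' Generate a coupled synthetic ECG + respiration record
#'
#' Beat times come from integrating an instantaneous heart rate
#' `hr_base * (1 + rsa_depth * sin(respiration phase))` to successive unit
#' thresholds, so respiratory sinus arrhythmia is exact by construction. The
#' ECG is a train of five-Gaussian PQRST templates with the R amplitude and
#' Q/S depths modulated by the respiration phase at each beat. The
#' respiration channel is a unit-amplitude sinusoid at the breathing rate
#' plus baseline wander, a delayed cardiogenic Gaussian ripple at each beat,
#' white noise and powerline interference. Ground-truth beat and breath
#' times are exact.
#'
#' @param cfg A [synth_config()].
#' @return A list: `record` (a [record()] with channels `ECG` and `RESP`),
#'   `beats` (truth R-wave [event_series()]), `breaths` (truth inspiration
#'   maxima), `config`.
#' @examples
#' rec <- generate_record(synth_config(duration = 60, seed = 7))
#' rec$record
#' length(rec$beats)
#' @export
generate_record <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  n <- round(cfg$duration * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  f_r <- cfg$rr_base / 60
  phase <- 2 * pi * f_r * t
  resp_clean <- sin(phase)

  # truth breath times: maxima of sin(phase)
  k <- 0:floor(cfg$duration * f_r)
  breaths <- (0.25 + k) / f_r
  breaths <- breaths[breaths < cfg$duration]

  # beat times: integrate-to-threshold on the instantaneous rate
  lambda <- cfg$hr_base / 60 * (1 + cfg$rsa_depth * sin(phase))
  cum <- cumsum(lambda) / cfg$fs
  nb <- floor(cum[n])
  beats <- numeric(nb)
  j <- 1L
  for (b in seq_len(nb)) {
    while (cum[j] < b) j <- j + 1L
    # linear interpolation between samples j-1 and j
    c0 <- if (j > 1L) cum[j - 1L] else 0
    beats[b] <- t[j] - (cum[j] - b) / (cum[j] - c0) * (1 / cfg$fs)
  }

  # ECG: per-beat PQRST with respiration-modulated R and Q/S amplitudes
  ecg <- numeric(n)
  tmpl <- pqrst_template()
  for (b in beats) {
    ph_b <- sin(2 * pi * f_r * b)
    lo <- max(1L, floor((b - 0.45) * cfg$fs) + 1L)
    hi <- min(n, ceiling((b + 0.50) * cfg$fs) + 1L)
    tt <- t[lo:hi] - b
    w <- numeric(length(tt))
    for (nm in names(tmpl)) {
      g <- tmpl[[nm]]
      amp <- g[2]
      if (nm == "R") amp <- amp * (1 + cfg$r_amp_mod * ph_b)
      if (nm %in% c("Q", "S")) amp <- amp * (1 + cfg$q_depth_mod * ph_b)
      w <- w + amp * exp(-(tt - g[1])^2 / (2 * g[3]^2))
    }
    ecg[lo:hi] <- ecg[lo:hi] + w
  }
  ecg <- ecg + cfg$ecg_noise_sd * stats::rnorm(n)
  if (is.finite(cfg$powerline_hz) && cfg$powerline_amp > 0)
    ecg <- ecg + cfg$powerline_amp * sin(2 * pi * cfg$powerline_hz * t)

  # respiration: tidal sinusoid + wander + delayed cardiogenic ripple + noise
  resp <- resp_clean +
    cfg$baseline_wander_amp * sin(2 * pi * 0.05 * t + 1)
  if (cfg$cardio_coupling > 0) {
    # R-wave-like mechanical spike: narrower than the 30 ms sharpening
    # frame (FWHM ~24 ms), as cardiogenic deflections in stretch signals are
    sigma <- 0.010
    for (b in beats) {
      c0 <- b + cfg$cardio_delay
      lo <- max(1L, floor((c0 - 5 * sigma) * cfg$fs) + 1L)
      hi <- min(n, ceiling((c0 + 5 * sigma) * cfg$fs) + 1L)
      if (lo > hi) next
      tt <- t[lo:hi] - c0
      resp[lo:hi] <- resp[lo:hi] +
        cfg$cardio_coupling * exp(-tt^2 / (2 * sigma^2))
    }
  }
  resp <- resp + cfg$noise_sd * stats::rnorm(n)
  if (is.finite(cfg$powerline_hz) && cfg$powerline_amp > 0)
    resp <- resp + cfg$powerline_amp * sin(2 * pi * cfg$powerline_hz * t)

  rec <- record(list(ECG = sampled_signal(ecg, cfg$fs),
                     RESP = sampled_signal(resp, cfg$fs)),
                metadata = list(origin = "synthetic", seed = cfg$seed))
  list(record = rec,
       beats = event_series(beats, label = "beat", source = "reference"),
       breaths = event_series(breaths, label = "breath",
                              source = "reference"),
       config = cfg)
}

#' Noise sweep with shared ground truth
#'
#' Regenerates the same record at several respiration-channel noise levels.
#' Beat and breath times are deterministic given the configuration, so the
#' truth series are identical across levels; only the noise differs.
#'
#' @param cfg A [synth_config()].
#' @param levels Numeric vector of `noise_sd` values.
#' @return A list of [generate_record()] results, one per level.
#' @export
snr_sweep <- function(cfg = synth_config(), levels) {
  lapply(levels, function(s) {
    cfg$noise_sd <- s
    generate_record(cfg)
  })
}
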