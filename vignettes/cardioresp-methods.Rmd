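---
title: "Methods: extracting heartbeats from respiration and respiration from ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting heartbeats from respiration and respiration from ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioresp)
```

## The problem

Cardiac and respiratory activity leak into each other's sensors. A
thoracic stretch or plethysmograph band records breathing, but small
cardiogenic oscillations — mechanical ripples synchronized with each
heartbeat — ride on top of the tidal waveform, strongest near the noise
floor and most visible during breath holds. Conversely, a single-lead ECG
is modulated by breathing through three mechanisms: respiratory sinus
arrhythmia (RSA) shortens the R–R interval during inspiration, chest
expansion changes electrode-to-heart distance (R-amplitude modulation),
and thoracic impedance changes alter waveform morphology (visible in the
Q-trough depth). This package turns each leakage channel into a signal:
`rdc()` locates heartbeat times in a respiration trace, and `edr()`
reconstructs a respiration waveform from beat-wise ECG features.

## The RDC model and its assumptions

The heartbeat detector needs an expected inter-beat interval before it can
search. It derives one from the breathing rate: the respiration signal is
band-passed to 0.2–0.5 Hz, breath peaks are located (minimum 2 s apart,
prominence at least 10% of the band-passed maximum), and the mean
breath-to-breath time is divided by an assumed **3 beats per breath**.
This ratio is the method's central physiological assumption; in real
supine adults it spans roughly 1.8–4, so the estimate can be ~30% off
without the detector failing, because the minimum-distance constraint it
feeds is itself relative (65%).

The cardiogenic ripple is then enhanced in seven deterministic stages:

1. band-pass 1–9 Hz (removes breathing, baseline wander, powerline);
2. subtract a 3rd-order Savitzky–Golay baseline whose frame length equals
   the expected inter-beat interval — this elongates and sharpens the R
   deflection without manufacturing peaks at breath crests;
3. subtract a 30 ms moving mean — the frame is chosen *longer than the R
   deflection but as long as the T deflection*, so merged R/T humps and
   T-wave oscillations deflate while the R spike survives;
4. add the mean absolute value (moves the trace positive);
5. square and amplify — by default the gain rescales the squared trace to
   the pre-squaring maximum; detection is scale-invariant, so any positive
   gain is equivalent;
6. band-pass 0.5–5 Hz;
7. clip negatives to zero.

Peaks of this trace at least 65% of the expected inter-beat interval apart
and above 8% of the trace mean are taken as beats, and each is shifted
**120 ms earlier** to compensate the electro-mechanical delay between the
R wave and its pressure ripple. "8% of the average height" is read as 8%
of the full processed-trace mean (not of the candidate peak heights); the
alternative reading is one config entry away (`height_frac` applies to
whatever statistic you supply it with).

A result is flagged `low_confidence` when the detected series is
implausible: beat count more than 50% off the expectation implied by the
interval estimate (the band is wide because the 3-beats-per-breath
assumption alone moves the count up to ~40%), or inter-beat-interval
coefficient of variation above 0.20. The CV criterion is what actually
catches noise: detections driven by band-limited noise under a refractory
constraint show IBI CV around 0.22–0.25, while sinus rhythm sits near
0.05; 0.20 splits the regimes with margin on both sides.

## The EDR model

Three modulation series are measured per beat:

- **R amplitude**: the ECG is band-passed 1–25 Hz, squared, smoothed twice
  with a 75-sample (0.3 s at 250 Hz) moving mean; peaks at least 160
  samples (0.64 s) apart with prominence ≥ 0.5% of the maximum are the R
  anchors, and their heights the amplitude series.
- **R–R interval**: consecutive anchor spacings, assigned to the interval
  midpoint (a symmetric choice; the anchor time is otherwise arbitrary).
- **Q-trough depth**: band-pass 0.1–25 Hz, keep only the negative lobe,
  invert, smooth three times (75-sample frame); peaks ≥ 10% of the maximum
  and ≥ 160 samples apart give the trough-depth series. Negating the ECG
  would swap the roles of R peaks and Q troughs — the two chains are
  mirror images around the baseline.

Each series passes the **300% rule**: with `m = mean(|values|)` computed
once, points with `|value| > 3m` are removed and the survivors divided by
`m`, making the three series unitless with mean magnitude ≈ 1 so no single
mechanism dominates the average. The cleaned series are cubic-spline
resampled onto the common sampling grid over their joint span, averaged
(the "averaged" step is read as division by 3; `average_mode = "sum"`
keeps the alternative reading where the subsequent moving mean is the only
averaging), smoothed with a 300-sample (1.2 s) moving mean and band-passed
0.15–0.5 Hz.

Against a reference respiration channel (despiked by replacing samples
more than 8 MADs from the median with the previous retained sample, then
band-passed 0.15–0.5 Hz, peaks ≥ 1 s apart with prominence ≥ 2.5% of
maximum), the composite is shifted by the best of {0, 0.2, …, 1.4} s —
minimizing the mean absolute nearest-peak distance — and each composite
peak is labelled: true positive within half a mean heartbeat period of an
unmatched reference peak, "inaccurate" within 50–100% of a heartbeat,
otherwise false positive; unmatched reference peaks are false negatives.
Only true-positive matches consume a reference peak, so TP + FN always
equals the reference count. The mean heartbeat period comes from the same
record's R–R series.

## Scoring and agreement metrics

`classify_beats()` matches greedily nearest-first with each reference
annotation usable once: |Δt| ≤ 140 ms is a true positive; an unmatched
detection 140–320 ms *after* some annotation is tagged `T_wave` (the
canonical failure mode of energy-based detectors); everything else is a
false positive. The two bookkeeping identities TP + FN = #reference and
TP + FP + T-wave = #detected hold by construction and are asserted in the
tests.

`window_rates()` counts events in half-open one-minute windows stepping by
10 s. `compute_metrics()` reports MAE, percentage error, NRMSE
(RMSE divided by the reference range — the defining formula is read as
carrying the radical, which the reported magnitudes require), Pearson's
ρ_p with a two-sided t-test (n − 2 df), and Lin's concordance

ρ_c = 2 s_rc / (S_r² + S_c² + (m_r − m_c)²),

with population (1/n) moments, which penalizes additive bias that ρ_p
ignores (|ρ_c| ≤ |ρ_p| always). A variant Pearson denominator with a
*difference* of squared deviations under an absolute value circulates in
print; it does not reproduce the correlation coefficient and is retained
only behind `pearson = "printed"` for audit.

`best_fit_align()` shifts the calculated events by the lag in ±3 s (0.1 s
grid) minimizing windowed MAE; zero is always a candidate, so alignment
never hurts. `waveform_correlation()` takes consecutive non-overlapping
32 s sections and the maximum normalized cross-correlation over lags
within ±3 s; note the max-over-lags statistic inflates the null (about
0.3 for independent signals band-limited to 0.15–0.5 Hz, with only ~22
effective samples per section), so values near 0.3 mean "unrelated", not
"weakly related".

## Numerical choices

- **Filtering** is zero-phase by construction: the signal is
  reflect-padded (even reflection, which keeps QRS spikes upright; length
  two cycles of the lower band edge) and multiplied in the frequency
  domain by the squared magnitude of an order-4 Butterworth band-pass —
  the exact response of a forward–backward pass. A cascaded time-domain
  transfer function is numerically unstable at bands like 0.2–0.5 Hz on a
  250 Hz grid, which is why the response is realized spectrally. A small
  warm-up transient in low bands is confined to the first/last couple of
  seconds of a record.
- **Savitzky–Golay** frames are rounded up to odd (warning) and floored at
  order + 2; the filter reproduces polynomials of the fitted degree
  exactly, which the tests assert at 1e−9.
- **Peak search** follows MATLAB `findpeaks` discipline: strict local
  maxima, height then topographic prominence thresholds, then greedy
  suppression tallest-first with ties keeping the earlier index. Plateaus
  (exactly equal neighbours) are not peaks.
- **Degenerate inputs** fail loudly with classed errors: band edges
  outside (0, fs/2), signals shorter than the filter warm-up, a breathing
  band holding only filter leakage (relative thresholds would otherwise
  "find" peaks in numerical residue), rectified signals with no negative
  lobe, non-overlapping modulation series.
- **Ties**: equal-height peak candidates keep the earlier index;
  equal-cost phase shifts keep the smaller shift.

## The synthetic generator

`generate_record()` produces the coupled two-channel records every
recovery test runs on. Beat times integrate an instantaneous rate
`hr_base·(1 + rsa_depth·sin φ)` (φ the respiration phase) to successive
unit thresholds, so RSA is exact by construction; the ECG is a train of
five-Gaussian PQRST templates with R amplitude and Q/S depth modulated by
`sin φ` at each beat; the respiration channel is a unit tidal sinusoid
plus 0.05 Hz baseline wander, white noise, powerline interference, and a
Gaussian cardiogenic ripple per beat, delayed 120 ms after the R wave and
only ~24 ms wide — narrower than the 30 ms sharpening frame, as the
mechanical R deflection must be for the RDC sharpening stage to make
sense. Defaults: 250 Hz, 5 minutes, 60 bpm, 15 breaths/min (4 beats per
breath, inside the observed 1.8–4 span), ripple amplitude 5× the
white-noise SD. One integer seed determines everything bit-for-bit.

What the generator does **not** emulate: breath-to-breath rate
variability, sensor drift and motion artifacts, ectopic beats, waveform
morphology changes, or the heteroscedastic noise of real stretch bands.
Recovery results on these records (sensitivity and precision above 95%,
median beat-timing error ~5 ms, windowed RR MAE ~0, waveform correlation
~0.996) therefore demonstrate that the pipelines are *correct* — they
recover exactly the structure they model, at realistic SNR — not that
real-world accuracy will match; published whole-database figures on real
recordings are far lower, dominated by atypical morphology and
heartbeat-to-breath ratios the fixed assumptions miss.

## Problem sizes used by the test suite

Unit and property tests run on 30–120 s records; the end-to-end recovery
and acceptance properties use ten 5-minute records per pipeline at 250 Hz,
a five-level noise sweep, 1,000 random rate-series pairs (n = 50) against
the metric oracle, 500 random beat-set pairs against the exhaustive
matcher, and 1,000 random signals against the exhaustive peak-search
oracle — sizes at which the brute-force oracles are still exact and the
whole suite runs in a couple of minutes on one CPU.

## Known limitations

- The assumed beats-per-breath ratio is fixed per record; adaptive
  updating from detected beats (and recursive search-back) is out of
  scope.
- The RDC pipeline degrades when the true heart rate drifts from the
  breathing-derived expectation within a record.
- The EDR composite adds the R–R series with the same sign as the other
  two components; under strong RSA its anti-phase contribution partially
  cancels (physiologically R–R lengthens during expiration), which the
  phase-alignment step cannot fully undo. With modest default RSA the
  in-phase components dominate.
- WFDB support covers header + signal formats 16 and 212 and MIT-format
  annotations — enough for the Fantasia-style two-channel records this
  package targets — not the full format zoo.
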