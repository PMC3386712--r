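---
title: "Detecting activity and inactivity in body-worn IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting activity and inactivity in body-worn IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Almost every application built on body-worn inertial measurement units —
inertial pedestrian navigation, posture estimation, activity classification —
needs to know, sample by sample, whether the wearer is moving or still.
Static intervals are when zero-velocity updates (ZUPT) can be applied and
sensor biases re-estimated; activity intervals are what classifiers segment
and label. `imudetect` implements nine detectors that turn a synchronized
triaxial accelerometer + gyroscope stream into a per-sample binary activity
marker, together with the machinery to benchmark them: a signal synthesizer
with exact ground truth, per-signal grid-search optimization, and a
Monte-Carlo driver.

All detectors share one workflow: a sliding window moves over the input
signal; each window position produces a scalar *figure of merit* `V(n)`;
`V(n) >= gamma` marks the decision instant active, `V(n) < gamma` static.
Frame decisions are broadcast back onto samples (a frame owns the `shift`
samples starting at its start index; trailing samples inherit the last
decision), so every detector yields a marker of the full signal length.

Units are g for acceleration (gravity = 1 exactly) and deg/s for angular
rate; both match MEMS datasheet full-scale ranges, and the g convention
makes the gravity-subtraction term of the acceleration-magnitude detector
dimensionless. Sample indices are 1-based throughout, R's native
convention.

## The detectors

**Magnitude family (time domain).** AMVD computes the within-frame variance
of the acceleration vector; it sees any fluctuation but is blind to
constant signals, and it anticipates transitions (a frame straddling an
onset already has high variance). AMD averages the squared deviation of the
acceleration magnitude from 1 g, scaled by the accelerometer noise variance
`sigma_a^2`; it cannot see rotations with no specific force. ARED averages
the squared angular-rate magnitude scaled by `sigma_w^2`; it cannot see
accelerations with no rotation. SHOD combines both: per frame it assumes
gravity lies along the frame-mean specific-force direction and adds the
noise-scaled acceleration deviation from that gravity estimate to the
noise-scaled angular-rate energy. When a frame's mean acceleration is
exactly zero the gravity direction is undefined and the term degenerates to
the raw squared magnitude (logged in code, covered by a test). The noise
variances are treated as known scaling factors; when not supplied they are
estimated as the variance of the magnitude residual over the first second
of the recording, which is assumed static.

FRD high-pass filters the input (removing gravity and drift), rectifies,
and low-pass filters into an activity envelope which is thresholded
per sample. The filters are 2nd-order Butterworth at 0.3 Hz (high-pass) and
0.5 Hz (low-pass) by default: the low-pass cutoff is chosen to smooth the
rectified signal over at least one gait cycle, otherwise ripple at twice
the cadence punches holes into detected activity. The default application
is **causal**, which is what a real-time implementation would do; it is
also what explains this detector's characteristic weakness — the envelope
lags onsets and decays past offsets, so every activity boundary contributes
errors. A `zero_phase` switch applies the filters forward-backward for
offline use.

**Spectral family.** The input series is framed (window `N`, advance
`shift`), optionally tapered (rectangular by default; Hann available),
zero-padded to `N_FFT = 512` bins and transformed; the figure of merit is
the band-averaged squared ratio of the spectrum to a reference noise
spectrum, in dB. The noise spectrum is the per-band mean of the first 10
frames (recordings are assumed to start at rest), floored at `1e-12` of its
maximum so that noiseless synthetic channels cannot produce divisions by
zero. FSD uses each frame's own spectrum; LTSD first takes the long-term
spectral envelope — the per-band maximum over `2J + 1` neighboring frames
(truncated at the boundaries) — which makes it robust to momentary dips
inside activity at the cost of smearing boundaries by up to `J` frames.
FSD is exactly LTSD at `J = 0`, an identity the tests assert.

**Memory family.** A buffer of the last `N` readings is scored over every
split into two adjacent sub-windows. MBGTD scores a split by the average
absolute distance between the two sub-windows' samples and takes the
maximal split; it is scale-dependent, so buffers inside an activity (large
spread) score high even without a distribution change. MBCD forms a
CUSUM-type log-likelihood ratio in which both sub-window densities are
Parzen (Gaussian-kernel) estimates, again maximized over splits. The
classic known-density CUSUM is included (`cusum_classic`) as the reference
this construction approximates; its alarm rule is `g_k >= h` with the
running minimum taken over `S_0 = 0, S_1, ..., S_k`.

Two numerical points matter for MBCD. First, kernel-weight sums are
accumulated directly and floored at `1e-300` before taking logarithms:
weights underflow for samples a few bandwidths apart, and computing window
sums by differencing running sums loses all precision exactly there (the
package's compiled scan and the brute-force oracle agree to `1e-10`
because of this). Second, the bandwidth. Re-estimating `lambda` per buffer
(e.g. Silverman's rule on the buffer) makes the statistic scale-invariant:
a buffer inside steady walking is as "homogeneous" as a static buffer, and
the detector sees only transitions — measured end-to-end accuracy collapses
to ~0.60. The package therefore fixes `lambda` per series at the series'
standard deviation: static buffers then have pairwise distances far below
`lambda`, weights near 1 and a statistic near 0, while active buffers
spread at the `lambda` scale. The per-buffer rule remains available for
the single-buffer `mbcd_fom()` and via the `parzen_lambda` override.

The flexible-input detectors (FRD, FSD, LTSD, MBGTD, MBCD) accept four
input combinations: the acceleration magnitude, the angular-rate magnitude,
their sum, or their product. The product is often strongest: activity
raises both magnitudes, so their product separates from the static floor by
the two factors multiplied. No rescaling is applied to the mixed-unit
combinations; the threshold grid absorbs scale.

## The synthesizer

Real benchmark recordings with trustworthy per-sample labels are expensive:
ground truth must be hand-labeled, and labeling hundreds of signals is
impractical. The synthesizer generates accelerometer-like and
gyroscope-like signals for seven activity kinds — walking, running,
jumping, sitting-down/standing-up, lying-down/standing-up, plus two
degenerate robustness probes (constant angular rate with no specific
acceleration, and constant acceleration with no angular rate) — with the
marker emitted by construction. Sequences alternate static and activity
segments, as in a stop-and-go exercise circuit; kinds are drawn with
weights 3 (walking), 2 (lie/stand), 1 (each of the rest), mirroring such a
circuit's composition; intensities (amplitude, frequency, duration) are
drawn uniformly from per-kind ranges.

Template choices, with their rationale:

* *Walking/running*: band-limited bursts — fundamental plus half-amplitude
  second harmonic with random per-axis phases on the accelerometer;
  a gyroscope oscillation at the cadence whose vector swings along one
  random spatial direction and reverses through near-zero each half-cycle
  (limbs stop and turn back), plus a 5% incoherent wobble. Walking
  1.4–2.5 Hz at 0.3–0.8 g; running 2.5–3.5 Hz at 0.8–2 g; gyroscope
  envelopes 30–300 deg/s.
* *Jumping*: a periodic cycle at 1.5–2.5 Hz of ground-contact impulse
  (raised-cosine, 30% of the cycle, 1.5–3 g), free-fall flight (the
  accelerometer reads ~0 g specific force, i.e. −1 g against gravity, 40%),
  and quiet stance; the gyroscope keeps oscillating throughout. The
  free-fall phase matters: without it the accelerometer is literally static
  between impulses while the marker says active, which no detector can
  reconcile.
* *Postural transitions* (1.5–3 s): one smooth biphasic push-off/brake
  transient acting along the instantaneous gravity direction, plus a single
  gyroscope lobe; the lie-down transition additionally rotates the gravity
  vector to a horizontal axis and back, with the gyroscope reading the
  consistent tilt rate.
* *Degenerate kinds* (1–3 s): brief events by design — a constant-rate
  rotation with the accelerometer reading pure gravity, and a constant
  specific-force offset with a silent gyroscope. They exist to punish
  single-sensor detectors, and they do: AMD misses 100% of the former,
  ARED 100% of the latter, AMVD both.

Static instants read exactly 1 g and 0 deg/s before noise. White Gaussian
noise (default 0.02 g and 1 deg/s per axis) is added and hard saturation
applied at ±3 g / ±500 deg/s, typical MEMS full-scale ranges. Activity
segments last 2–6 s, static segments 2–5 s, all uniform.

What the synthesizer does **not** emulate: stride-to-stride intensity
variability, soft-tissue artifacts, orientation drift during level
activities, sensor bias instability, or colored noise. Detection on these
signals is consequently somewhat easier than on real recordings — static
and active periods are cleanly separated at high SNR — so the benchmark's
absolute accuracies should be read as an upper bound, and very short
optimal windows (often 2 samples) are an artifact of that cleanliness:
nothing inside a synthetic activity ever dips to the static floor for long
enough to fool a 2-sample window, while real signals force windows of
~10–20 samples. Relative detector ordering is the robust output.

## Evaluation protocol

Per-sample accuracy (fraction of samples matching the truth marker) and the
phi coefficient (Pearson correlation of the binary vectors; defined as 1
for identical constant vectors and 0 for non-identical ones with a constant
side) measure agreement. `grid_search()` sweeps each detector's parameter
grid — windows 2–40 plus a sparse tail to 100 samples for the magnitude
family (AMD optimizes near two-second windows), window × shift for the
spectral family with envelope orders 0–3 for LTSD, buffers of 3–20 samples
for the memory family, threshold-only for FRD — and at every grid point
sweeps 40 thresholds spanning the observed figure-of-merit range
(log-spaced when the statistic is strictly positive, linear otherwise,
e.g. for dB-scale statistics). The per-signal maxima of accuracy and
correlation are recorded, with the parameters attaining the accuracy
maximum; accuracy ties break toward smaller window, then smaller threshold,
preferring lower detection latency. `monte_carlo()` repeats this over
freshly synthesized recordings (per-repetition seeds derived
deterministically from one master seed) and reports mean ± unbiased SD.

ROC curves sweep the threshold over every distinct per-sample score;
per-repetition curves at the accuracy-optimal window are averaged
vertically on a 0.01-spaced false-positive-rate grid, and the area under
the mean curve is reported by trapezoid. The trapezoidal AUC is checked
against the Mann–Whitney rank formulation, and against `pROC`, in the
tests.

Problem sizes: the packaged tests and the `scripts/acceptance.R` benchmark
use 50 Monte-Carlo repetitions of recordings with 8 activity segments
(~60 s at 50 Hz, ~3000 samples); oracle-equivalence tests run buffers up to
15 samples and recordings up to 2000 samples. These sizes put the mean
accuracy's standard error well below the tolerances being checked while
keeping a full run in minutes.

## Known limitations

* The degenerate-kind fractions and template morphologies are this
  package's own choices; absolute accuracies shift by a few percent under
  other defensible choices, relative orderings much less.
* MBCD's statistic is sensitive to its bandwidth convention (see above);
  comparisons across implementations must fix that convention first.
* The FRD default is causal; zero-phase filtering raises its measured
  accuracy and removes its boundary lag, so the two variants are not
  comparable.
* Grid searches optimize accuracy per signal; parameters transferred across
  signals (a deployment scenario) will do worse than the reported
  per-signal maxima.

## A minimal session

```r
library(imudetect)

rec <- synth_imu(n_activities = 4, seed = 7)
det <- run_detector(rec, "shod", detector_config(window = 10, threshold = 10))
marker_accuracy(det$marker, rec$truth_marker)

gs <- grid_search(rec, "shod")
gs$best

bench <- monte_carlo(c("shod", "amd"), n_runs = 10, seed = 1)
bench$summary
```
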