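---
title: "Infant sleep staging from a waist-worn IMU: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Infant sleep staging from a waist-worn IMU: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Polysomnography (PSG) is the gold standard for infant sleep assessment but
is confined to the sleep laboratory. A small inertial measurement unit (IMU)
worn on the front waistline — a triaxial accelerometer (±8 g, m/s²) and
gyroscope (±500 °/s) sampled at 13 Hz — captures three signals that track
vigilance state in infants: body movement, abdominal respiration, and body
posture. `imusleep` implements the analysis stack for such recordings:
per-epoch feature extraction that can run identically inside the sensor or
offline, a three-state sleep classifier (Wake, N1/REM, N2/N3), and a
continuous Sleep Depth Trend (SDT) for visualising sleep architecture
across the night.

The three-state target is deliberate. Separating REM from N1 reliably needs
eye-movement and muscle-tone channels, and separating N2 from N3 needs EEG;
a movement sensor can realistically track the *depth* axis of sleep —
wake, light sleep (N1/REM), deep sleep (N2/N3) — on the standard 30-s
scoring grid.

## Features (per 30-s epoch, 390 samples)

* **Activity** — the mean Euclidean norm of the gravity-removed
  acceleration, computed on six 5-s sub-windows (65 samples) and averaged.
  Gravity is removed by subtracting the sub-window mean vector rather than
  with a long high-pass filter: that choice is exact for static windows,
  has no warm-up state, and therefore produces bit-identical results in
  streaming and batch computation. Units: m/s².
* **Four respiration parameters from the gyroscope.** Each gyro axis is
  band-pass filtered to 0.3–1.5 Hz (18–90 breaths/min — wide enough for
  infant respiratory rates across 0–18 months) with a 4th-order recursive
  Butterworth cascade applied forward and backward (zero phase). The axis
  retaining the largest fraction of its variance in band is the
  respiration source; an epoch with no axis above 50 % in-band variance is
  flagged invalid. From the selected signal:
  * `resp_autocorr` — the maximal normalized autocorrelation over lags
    0.67–3.33 s (9–43 samples). This doubles as the quality-control value.
  * `resp_rate` — 60 / (lag of that maximum in seconds), in breaths/min.
  * `resp_amplitude` — the RMS of the band-passed signal, in °/s.
  * `resp_variability` — the coefficient of variation of successive
    positive-going zero-crossing intervals (0 when fewer than 3 intervals).
* **Posture code** — the canonical device-frame direction (1 left side,
  2 supine, 3 right side, 4 prone, 5 head down, 6 head up) with the
  smallest angle to the mean acceleration vector; ties break to the lowest
  code. Epochs whose mean acceleration norm falls outside 0.5–1.5 g are
  movement-dominated and carry the neighbouring epoch's code.
* **`qc_valid`** — FALSE when the autocorrelation peak is below 0.4, when
  no gyro axis is respiration-dominated, or when the movement-dominated
  posture rule fired.

The exact formulas behind the deployed sensor's feature set are not
public; the four respiration parameters above are this package's declared
reconstruction, chosen so that each is independently testable (forced
sinusoid periods, closed-form RMS, controllable zero-crossing CV).

### Numerical choices

* *Octave correction for the rate estimator.* A periodic signal's
  autocorrelation peaks equally at its true lag and at multiples of it, so
  the global maximum can land on the subharmonic (half the breathing
  rate). The estimator steps down to the half lag whenever its correlation
  reaches 90 % of the current peak — the standard pitch-detection octave
  fix. For a genuine slow breather the half-lag correlation is strongly
  negative, so the correction never fires spuriously.
* *Rate quantization.* Rates are quantized to 780/k bpm for integer lags
  k; near 40 bpm the quantum is about 2 bpm. Tests therefore assert "within
  one lag quantum", not exact equality, whenever noise is present.
* *Zero-phase filtering* uses odd-reflection padding of 60 samples
  (~4.6 s) with zero initial filter state; transients decay well inside
  the padding at these cut-offs.
* *QC threshold 0.4* for the autocorrelation peak: the original deployment
  names autocorrelation as the quality-control parameter but publishes no
  threshold; 0.4 is this package's choice and is exposed in
  `feature_config()`.

### Streaming/batch equivalence

In-sensor logging must produce the same feature log as offline computation
on the raw stream. Every per-epoch computation here sees exactly its own
390 samples and nothing else, and the only cross-epoch step (posture
carry-forward and the QC rule) runs in a shared finalization pass, so
`extract_features_streaming()` is bit-identical to `extract_features()`
under *any* chunking of the stream. This holds as a property test over
randomized chunkings, and is the design reason for window-mean gravity
removal and per-epoch filtering.

## Normalization

The five classifier features are robust-z scored — centered at the median,
scaled by the IQR — with activity passed through `log(1 + x)` first (its
distribution is heavily right-skewed by movement bursts). Parameters are
estimated on training recordings only. Invalid epochs have their missing
respiration values imputed by carrying the last valid value (backfilled at
the start) so the epoch grid stays aligned with the hypnogram; the QC flag
is preserved for downstream masking. An optional per-subject mode
re-estimates center and scale from each recording's own valid epochs at
application time (no training-data leakage); it is off by default because
subject-wise normalization brought little improvement in the deployed
model, but is exposed for cohorts with large between-subject baseline
shifts. The original "combination of methods" used in deployment is not
public; robust z-scoring plus log-activity is this package's declared
substitute.

## The classifier

A bidirectional GRU with two layers of 10 hidden units per direction and a
3-class softmax head, reading the five normalized features per epoch. Each
recording is one full training sequence — no fixed-length windowing — so
the bidirectional context spans the entire night in both directions. The
network, backpropagation through time, and the Adam optimizer are
implemented in compiled code inside this package (no deep-learning
framework exists in the target environment); the analytic gradients are
verified against central finite differences in the test suite, which is
the load-bearing correctness check for everything downstream.

Training minimizes the 3-class cross-entropy, full-batch, with Adam at
learning rate 1e-3, at most 300 passes, and early stopping (patience 20)
on an inner recording-level 80/20 split. These optimizer settings are not
specified by the deployment this re-implements; they are conservative
choices for a ~2900-parameter model and are all exposed in
`model_config()`. Class weighting (inverse-frequency) is implemented but
off by default — it was evaluated and brought no overall improvement — and
the infant's age is deliberately not an input for the same reason.
Training is deterministic given the seed: initialization uses a dedicated
RNG, and full-batch updates have no ordering stochasticity.

Evaluation uses leave-one-subject-out cross-validation (LOSOCV): for each
recording, the normalizer and the model are fitted on all other recordings
only, then applied to the held-out one — no test-fold leakage by
construction. One master seed fans out deterministically to per-fold
seeds. Performance is summarized per recording by accuracy and the
multiclass Matthews correlation coefficient, with group medians and IQRs
(type-7 quantiles, pinned for reproducibility) and a pooled-epoch
confusion matrix. Pooling epochs (rather than averaging per-recording
matrices) is this package's documented choice for the group matrix.

## Sleep Depth Trend

The SDT maps each epoch's class probabilities to a continuous depth:
0·p(Wake) + 1·p(N1/REM) + 2·p(N2/N3), smoothed with a centered moving
average (default 5 epochs = 2.5 min; the window shrinks at the edges so
smoothed values never leave the convex hull of the raw depths they
average). The confidence track is the per-epoch maximum class probability,
in [1/3, 1], smoothed identically; night reports shade a band of
half-width (1 − confidence) around the trend. The published description of
the SDT is qualitative; depth values 0/1/2 and the 5-epoch window are the
minimal faithful realization here and are exposed in `compute_sdt()`.
Discretizing probabilities to a hypnogram takes the arg-max with ties
broken toward the shallower state.

## The synthetic cohort: what it does and does not establish

No public recordings exist for this device, so the package ships a seeded
simulator that serves as the test substrate for every other module. It is
a *stated world*, not a tuning knob: the default "separable" scenario
fixes the physiological contrasts the features target, with effect sizes
large enough for stable tests.

* Sleep architecture: a semi-Markov chain (explicit dwell-time
  distributions, no self-transitions) — truncated log-normal dwells with
  means 5/12/20 min (SD 3/6/8) for Wake/N1REM/N2N3 and transition weights
  that forbid direct Wake→deep transitions. Infant sleep cycling has dwell
  structure that a geometric-dwell Markov chain misrepresents, hence the
  semi-Markov choice.
* Respiration: a renewal process of per-breath periods (gamma-distributed,
  state-dependent mean rate 45/38/30 bpm and interval CV 0.30/0.25/0.08)
  driving a quasi-sinusoid on the gyroscope pitch axis with state-dependent
  amplitude 2/5/8 °/s. Modelling breaths as a renewal process (rather than
  a frequency-modulated sinusoid) makes the zero-crossing-interval CV a
  directly controllable ground truth.
* Movement: state-dependent Poisson bursts (6/1.5/0.2 per min) as smooth
  Gaussian pulses on both sensors; posture changes as a 1/h Poisson
  process, each co-occurring with a large burst (the "turn" artefact).
* Sensor floor: white noise (0.05 m/s², 0.5 °/s) and hard clipping at
  ±8 g / ±500 °/s, with clipped samples counted.
* Cohort structure: per-recording seeds derive from the master seed and
  each subject gets a respiration-rate offset (SD 2 bpm) to create
  realistic between-subject variation for LOSOCV.

A green end-to-end test on this world establishes that the pipeline
recovers states whose feature signatures match its design assumptions, at
realistic noise levels, with no leakage and full determinism. It does
*not* establish clinical accuracy: real infant recordings contain cardiac
and vibration artefacts, non-stationary breathing, unmodelled postural
dynamics, and scorer disagreement, none of which the simulator emulates.
The published performance figures on clinical PSG co-recordings (median
accuracy 78 %, median MCC 0.65) come from data that is not publicly
available and are therefore not reproduced here; the package's acceptance
checks are property-based instead.

## Degenerate inputs and edge rules

* Streams with sampling gaps refuse to load by default (`on_gap =
  "split"` returns gap-free segments); silent interpolation would corrupt
  the respiration features.
* Trailing partial epochs are discarded, matching the 30-s scoring grid.
* A constant (degenerate) feature gets scale 1 and a warning from the
  normalizer instead of dividing by zero.
* A recording with no valid epochs still yields probabilities (callers may
  mask), flagged `all_invalid` in metadata.
* Per-class recall for a class absent from the truth is reported as
  missing, never as zero.
* Multiclass MCC is defined as 0 when a denominator factor vanishes (e.g.
  all predictions in one class).
* Applying the normalizer twice is an error, not a silent second scaling.

## Known limitations

* The respiration-rate resolution is bounded by the autocorrelation lag
  quantum (~2 bpm near 40 bpm at 13 Hz).
* The posture frame assumes the standard mounting orientation (X toward
  the infant's left, Y toward the head, Z anterior); other mountings need
  an axis remapping before feature extraction.
* The classifier cannot separate REM from N1 or N2 from N3 — by design.
* Monte-Carlo recovery tests in the suite run at reduced replicate counts
  (e.g. 2000 instead of 10⁴ simulated nights for dwell recovery) to keep
  the default test run fast; the assertions hold with margin at those
  counts because the Monte-Carlo standard error is several times smaller
  than the tolerance.
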