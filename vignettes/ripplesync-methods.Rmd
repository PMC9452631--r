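---
title: "Methods: dual-region sharp-wave ripple detection and coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-region sharp-wave ripple detection and coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ripplesync)
```

`ripplesync` analyzes simultaneously recorded local field potentials (LFP)
from hippocampal CA1 and medial entorhinal cortex (MEC) to detect
sharp-wave ripples (SWRs), characterize them, and quantify how SWR timing
is coordinated across the two regions. This vignette is the package's own
account of what each stage computes, why each default is what it is, and
what the bundled synthetic generator can and cannot tell you about real
data.

## Signal model and conventions

An LFP trace is a finite, uniformly sampled voltage series in microvolts
with an explicit sampling rate (nominally 2000 Hz for tetrode recordings,
never hard-coded), a start time, and a region label. All times are seconds
from session start; sample `i` (0-based) sits at `t0 + i/fs`, and event
intervals are half-open `[start, end)`. Positions are in cm from 50 Hz
overhead LED tracking; when two head-stage LEDs are present the head
position is their midpoint — the tracking literature offers no single
convention, and the midpoint is the symmetric choice.

File I/O is deliberately plain: CSV for traces, positions and event
tables; schema-versioned JSON for correlograms and Granger results. Every
writer/reader pair round-trips losslessly (times preserved far below the
1 ns level). Vendor acquisition formats are an extension point, not core:
plain-text inputs keep the artifact self-contained and inspectable.

## Immobility gating

SWRs are a resting-state phenomenon, so detection is restricted to
immobility. Running speed is computed from LED positions smoothed with a
0.4 s boxcar (suppressing fix-to-fix tracker jitter at 50 Hz; set
`smooth_window = 0` to disable) and differentiated by central differences.
The immobility mask holds the last speed fix (previous-value hold, so the
mask is piecewise constant between 50 Hz fixes) and marks samples with
speed strictly below 2 cm/s. LFP samples outside the tracked range count
as mobile. Total immobile time — the denominator of SWR density and the
cross-correlogram normalizer — is the mask's true-sample count divided by
the LFP rate. Whether any speed smoothing or hysteresis should surround
the 2 cm/s criterion is genuinely open; we use the strict threshold with
position (not speed) smoothing, and both knobs are exposed
(`motion.speed_threshold_cm_s`, `motion.smooth_window_s` in pipeline
configs).

## Ripple-band envelope and detection

The trace is band-passed to 150–250 Hz with a 4th-order Butterworth
applied forward and backward (zero phase — any phase lag would bias the
cross-regional timing measurements this package exists for). The analytic
signal is constructed by the standard FFT method; its magnitude is the
ripple envelope. The envelope is z-scored with mean and SD estimated over
the whole session by default (`norm_epoch = "immobile_only"` is
available); the first and last 0.5 s are excluded from that estimation,
and events peaking in those margins are discarded outright — zero-phase
filtering and the circular FFT leave boundary transients there that no
padding fully removes (we reflect-pad both the filter and the analytic
transform, which suppresses but cannot eliminate them), and real pipelines
should not interpret recording edges anyway.

Detection is a threshold rule: maximal runs of samples with `z > 5` become
events. Two numerical choices surround it:

* **merge gap, 10 ms** — the envelope of a single physiological ripple can
  dip briefly below threshold; runs separated by less than the gap are
  fused. 10 ms is well below the inter-event refractory spacing but above
  one ripple cycle (4–7 ms at 150–250 Hz).
* **minimum duration, 5 ms** — an event shorter than one ripple cycle is
  noise; this also removes single-sample threshold grazes.

Both are recorded in the event table's metadata and are configurable; the
duration definition itself (time spent above 5σ, no secondary boundary
threshold) follows the classical definition, with an edge-threshold
variant deliberately left out of the default path. The immobility gate
applies to the *envelope peak sample* of each event, the least destructive
reading of "restricted to immobility": an event straddling a mobility
transition is judged by its center, not its tails. Amplitude is reported
as peak envelope z; detection is invariant to amplitude scaling and DC
offset of the raw trace, which the tests assert directly. The envelope
(not its square) is the default z-variable, with `squared = TRUE`
available — the two differ only monotonically, so thresholding at matched
quantiles is equivalent; 5σ on the envelope is the conservative reading.

Per-event spectra use a Hann-windowed periodogram of the *raw* snippet,
padded symmetrically to at least 64 ms so that 150–250 Hz is resolved by
several bins; mean power is the average of `10·log10(PSD)` over in-band
bins (dB/Hz), and the frequency peak is the argmax bin. Sharp waves are
detected independently with the same envelope-threshold machinery on the
1–50 Hz band, and a ripple is flagged co-occurring when a sharp-wave peak
falls within ±30 ms of the ripple peak (peak-to-peak — the window's anchor
point is otherwise ambiguous).

## Cross-regional coordination

The cross-correlogram counts MEC event peaks in a ±100 ms window around
each CA1 event peak, in 5 ms bins, normalized by total immobile time.
Negative lags mean MEC precedes CA1. 5 ms bins resolve lag differences of
the size that separates healthy from impaired coordination (~10 vs ~25 ms)
while keeping per-bin counts stable; events enter by envelope peak time,
the same anchor used everywhere else. Peak lag is extracted after a 3-bin
boxcar (raw peak available via `smooth_bins = 1`); ties break toward the
smallest |lag| and then toward the MEC-leads side, so a symmetric
correlogram reports the physiologically prior reading. An all-zero
correlogram has no peak and returns `NA` rather than a fabricated lag.
Binning is symmetric (`round`), so swapping reference and target mirrors
the correlogram exactly — a property the tests check against a brute-force
double loop.

## Granger causality on sparsified envelopes

The envelope z series is sparsified — values kept where `z > 5`, zero
elsewhere, with *no* immobility gating (gating would fragment an already
sparse series) — and fed to a bivariate VAR fit by conditional least
squares at the native LFP rate, so an order-50 model spans 25 ms of
history. Model order is chosen in 1–50 by AIC or BIC on a common sample
(all candidate fits condition on the same 50-sample presample, making the
criteria comparable; ties go to the smaller order). Each direction is
tested with the nested F statistic
`F = ((RSS_r − RSS_f)/p) / (RSS_f/(N − 2p − 1))`, and binary significance
calls are made after Benjamini–Hochberg FDR correction across each
session's full family of tests (all pairs × both directions — the natural
family for a session-level analysis). Pairs whose sparse series are empty
are excluded and logged rather than coerced to 0. The detection σ is
reused for sparsification rather than recomputed without the velocity
restriction; with whole-session normalization the two coincide.

### What the directed-influence test can and cannot conclude

A finding from this package's own validation, stated plainly because it
affects interpretation: on synthetic sessions with event-level coupling
(MEC bursts leading CA1 bursts by ~9 ms), the nested-F test returns
*significant causality in both directions* for essentially every coupled
pair at realistic session lengths. The forward (MEC→CA1) direction
carries burst-onset prediction and shows F statistics 3–10× larger than
the reverse; but the reverse direction is also genuinely informative in
the linear-prediction sense — the trailing CA1 burst improves the model of
the MEC burst's decay and post-event silence (the reverse RSS reduction
localizes 3–40 ms *after* MEC peaks). This is not an implementation
artifact: our F statistics match an independent Granger implementation to
three digits. Consequently, with hundreds of thousands of samples the
*binary* significance rate saturates at 1 in both directions whenever
coupling exists, and group contrasts built on binary rates can only
discriminate direction when coupling is weak or data are short. The
directional asymmetry itself is robustly carried by the F-statistic
magnitudes, which the validation studies report as a forward/reverse
F-ratio. Analyses of real recordings should expect fractional
significance rates only because real coupling is far weaker and noisier
than the generator's; equality of binary rates across directions does not
imply absence of directed asymmetry.

The white-noise null is well calibrated: across 1000 independent
white-noise pairs the raw per-direction rejection rate at α = 0.05 is
0.05 within binomial error, and a VAR(3) simulation recovers its order by
BIC in well over 90% of runs.

## Group statistics

Electrodes are the statistical unit, with per-electrode values averaged
over sessions first. Group comparisons use the Wilcoxon rank-sum test —
exact null distribution when `n_a + n_b ≤ 20` without ties, normal
approximation with tie and continuity correction otherwise — and the
two-sample Kolmogorov–Smirnov test for distributional shape. Both are
rank-based, hence invariant to monotone transforms, and are checked
against full-enumeration and ECDF-sweep oracles. A helper reproduces the
sex-pooling protocol (compare sexes within groups first; pool when
non-significant). Duration structure is summarized as a normalized
duration histogram and its cumulative curve, with the long-ripple fraction
defined strictly (`duration > 25 ms`).

## The synthetic generator

`generate_session()` produces paired CA1/MEC sessions with known ground
truth: 1/f background noise (exponent 1.0, SD 30 µV — typical awake-LFP
broadband levels; the spectral shaping is capped below 1 Hz to keep
finite power), Gaussian-envelope ripple bursts at 200 Hz whose FWHM is
lognormal (median 30 ms, log-SD 0.35, spanning ~15–60 ms), biphasic
sharp-wave transients co-injected with probability 0.95, an alternating
30 s mobile/immobile schedule realized in the 50 Hz position track, CA1
events as a Poisson process (default 0.1/s of immobile time) confined to
immobile epochs with a 0.25 s refractory spacing, and MEC events of which
a configured fraction are placed at the CA1 time plus a jittered lag.
Cohort presets encode the two regimes of interest: `"wt"` (coupled
fraction 0.8, lag −8.9 ± 5 ms — MEC leads) and `"ad"` (coupled fraction
0.5, lag +23.2 ± 5 ms — MEC trails). The default burst amplitude of 8×
noise SD puts detection in a comfortably supra-threshold regime. A single
seeded RNG stream makes sessions bit-identical under the same seed.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: biophysical waveform diversity (real
ripples are neither Gaussian-enveloped nor fixed-frequency), non-ripple
high-frequency artifacts (EMG, chewing), electrode drift and referencing
effects, state transitions other than a clean mobile/immobile alternation,
and common-drive coupling (coupling is implemented at event-time level so
ground-truth lags are exact; a filtered common-input alternative would
blur them). Detection performance on the generator is an upper bound, not
a forecast, for real recordings.

## Validation studies and problem sizes

The `study_*()` functions run the standard self-validation battery, sized
so the whole battery completes in minutes on one CPU:

* `study_detection()` — one 1800 s session at 0.1 events/s and 8× noise
  SD; recall and precision vs ground truth (greedy one-to-one peak
  matching within 20 ms) both reach 1.0, and detected density matches
  truth-derived density.
* `study_null_rate()` — 600 s ripple-free session; false detections stay
  below 0.01 events/s (typically zero; single-sample threshold grazes are
  removed by the minimum-duration rule).
* `study_duration_recovery()` — ~200 matched events spanning 15–60 ms
  widths; Spearman ρ ≈ 0.99 between estimated durations and injected
  FWHMs. (Estimated durations exceed FWHMs systematically — time above 5σ
  is wider than the half-maximum width for strong bursts — which is why
  the check is rank-based.)
* `study_lag_recovery()` — 100 event-level sessions per preset; the
  correlogram peak lag lands within one 5 ms bin of the injected lag in
  ~100% of runs for both presets.
* `study_gc_directionality()` / `study_gc_null()` — 20 simulated pairs
  (240 s each) for the coupled study, 1000 white-noise pairs for
  calibration; see the directed-influence discussion above.
* `study_sw_cooccurrence()` — ≥400 events with 90% sharp-wave
  co-injection; the measured co-occurrence percentage recovers 90% within
  sampling error. The study uses ~400 events rather than the minimal 200
  because a ±3-point check on a 90% proportion needs that many events for
  the band to sit at ~2 standard errors.

`scripts/acceptance.R` runs the same battery from a single seed and writes
the numbers as JSON.

## Known limitations

* Electrodes are treated as independent units; electrode-within-animal
  nesting is not modeled (a mixed-effects extension would be the next
  step).
* The cross-correlogram reports the argmax bin; sub-bin lag estimation
  (e.g., parabolic interpolation) is not implemented, so lags are
  quantized to 5 ms by default.
* Binary Granger significance saturates under strong coupling (discussed
  above); magnitude-based asymmetry is reported alongside.
* No vendor format readers (Neuralynx NCS/NVT) and no spike-train
  analyses; the package starts from continuous LFP and position tables.
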