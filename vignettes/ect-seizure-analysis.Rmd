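---
title: "ECT seizure detection and quality indices: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECT seizure detection and quality indices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented by
`ictal`, the choices made where the underlying method leaves room, and
what the synthetic simulator does and does not establish about real
clinical recordings.

## Signal model and segmentation

Input recordings are one- or two-channel scalp EEG at 200 Hz, amplitudes
in µV, with a known end-of-stimulation time. Time is measured in seconds
from the first sample and every window is half-open `[start, end)`.
Records are cut into non-overlapping windows of 1.28 s (256 samples),
a compromise between temporal resolution for rapid ictal transitions and
spectral resolution (bin width 200/256 ≈ 0.78 Hz). The trailing partial
window is dropped rather than zero-padded so all windows share one
spectral resolution. Recordings longer than 120 s are excluded with a
countable status rather than an error, because batch analyses need the
exclusion tally. Records not sampled at 200 Hz are rejected rather than
resampled; resampling is out of scope.

Optional preprocessing reapplies the acquisition device's filters (50 Hz
notch, 30 Hz lowpass) as zero-phase forward–backward Butterworth passes.
Zero-phase filtering is deliberate: endpoint timing must not be biased by
filter group delay. Exported recordings usually carry the device filters
already, so preprocessing defaults to off in the pipeline configuration.

## Reference labelling

For supervised training, windows are labelled from a reference endpoint
(a device or an expert): windows overlapping the stimulation interval are
omitted; post-stimulation windows starting before the reference endpoint
are ictal, the rest non-ictal. Two conventions had to be fixed:

* **Straddling window**: the window containing the endpoint is labelled
  by its start time (ictal iff it starts before the endpoint). Any
  convention misassigns at most one window per record.
* **Missing endpoint**: all post-stimulation windows stay unlabelled and
  are excluded from training, since their true state is unknown.

## Features and filters

Each window yields 34 features spanning two families: spectral
frequency/energy descriptors (absolute and relative power in δ 0.7–3.5,
θ 3.5–8, α 8–13, β 13–25 Hz; total 0.7–25 Hz power; spectral centroid,
entropy, spread; dominant and median frequency) and time-domain
statistics (mean, variance, SD, skewness, excess kurtosis, RMS, mean
absolute amplitude, peak-to-peak, IQR, median, zero crossings, line
length, Hjorth mobility and complexity, energy, slope-sign changes,
lag-1 autocorrelation, sample entropy with m = 2 and r = 0.2·SD, mean
absolute first/second differences). The set is a documented default, not
a canonical list; it is chosen to cover the named families and is
order-stable so tables are reproducible. Degenerate inputs are defined
by limit conventions (skewness/kurtosis of a constant window are 0;
spectral shape descriptors of a zero-power window are 0) so feature
tables never contain NaN. The window mean is removed before the windowed
FFT so DC offset cannot leak into the δ band through the Hanning main
lobe.

Two filters prune the features before training:

* **Low variance**: each feature is min–max scaled to [0, 1] for
  assessment; features with scaled variance ≤ 20% of the maximum
  attainable for a [0, 1] variable (0.25, achieved by a balanced 0/1
  column) are dropped. "Variance ≤ 20%" is not meaningful without a
  reference scale; the maximum-attainable-variance reading makes the
  threshold dimensionless and scale-free, and it is configurable.
* **High correlation**: a greedy scan in feature order drops the later
  member of any pair with |Pearson r| ≥ 0.95. The greedy-by-order rule
  makes the filter deterministic; its output is invariant to row order
  and to affine rescaling of any feature.

Variance filtering precedes correlation filtering, matching the order in
which the criteria are stated for the method.

## Classification pipeline

Training rows are balanced by random undersampling of the majority class
and split 8:2 with per-class stratification (the split method is
otherwise unspecified; stratification is the conservative choice for a
balanced design). Min–max scaling and PCA are fitted on training rows
only; the retained component count is the smallest whose cumulative
explained variance reaches 80%. Test values may leave [0, 1] when
outside the training range — this is intentional, the alternative
(clipping) discards information.

Five classifier families are supported: decision tree (`rpart`,
information criterion), random forest (`randomForest`), RBF-kernel SVM
(`e1071`, including the γ = 1/(d·Var x) "scale" convention), k-nearest
neighbours (`class`), and gradient boosting (`xgboost`). Hyperparameters
are tuned by exhaustive grid search, scored by the mean Matthews
correlation coefficient over 5 stratified cross-validation folds. MCC is
the primary score because it is balanced in both error types even when
class balance drifts inside folds. Ties break to the first cell in
declared grid order, and a cell that fails to fit scores −1 for that
fold instead of aborting the search; the total fit count is recorded.
The default grids are small and centred on hyperparameter ranges that
published ECT-segment classifiers retain (e.g. C = 10 with an RBF kernel
is reachable); reproducing thousands-of-fits grids is pointless without
knowing the original grids, and the search machinery is independent of
grid size.

Evaluation reports confusion counts, accuracy, per-class and weighted
precision/recall/F1, MCC, and ROC-AUC from predicted probabilities.
Classifier families are compared on the shared test set by Cochran's Q
over their per-item correctness indicators and pairwise McNemar tests
(continuity-corrected χ², with the exact binomial fallback below 25
discordant pairs).

## Onset and endpoint rules

The per-window ictal probability trace is converted to an annotation as
follows. Onset: the start of the first run of at least ⌈8/1.28⌉ = 7
consecutive windows with p > 0.5, beginning at or after stimulation end.
Eight seconds is not a whole number of windows; 7 windows (8.96 s)
guarantee the "at least 8 s" reading, and the count is configurable.
Endpoint: the start time of the first window of the first subsequent run
of 3 consecutive windows with p < 0.3 — the first non-ictal epoch, not
its end. If a complete onset run begins within 4 s after a candidate
endpoint, detection continues and the later endpoint is retained; the
recurring run may extend beyond the window. Both thresholds are strict
inequalities; boundary probabilities do not qualify. A trace with no
qualifying onset run is `no_seizure`; a record ending before an endpoint
run completes is `truncated_recording`, mirroring the clinically common
case of recordings stopped right after the seizure.

A useful consequence of the rule structure (proved by the relative sizes
of the onset run, endpoint run and recurrence window): raising the
endpoint threshold can only shorten the detected seizure, never lengthen
it. This monotonicity is asserted as a property test.

## Quality indices

All amplitude indices use channel 1; COH requires both channels. The
ictal window set of a record is the segment grid aligned to t = 0
restricted to windows wholly inside `[onset, endpoint)`.

Decisions where the index definitions leave room:

* **ASEI** is computed in the time domain (mean squared ictal amplitude),
  which has the stated µV² units directly; a PSD-sum variant is available
  behind a flag for sensitivity analysis.
* **EIA**'s "initial phase" is the first 8 ictal windows (≈ 10.24 s),
  matching MIA's window length so the two are comparable; with fewer
  than 8 ictal windows EIA/MIA/MSP are missing (`ictal_too_short`).
* **PSI** compares the mean |x| of the *last three* ictal windows wholly
  before `endpoint − 4 s` (the closest comparable ictal activity) with
  the *first three* windows wholly after `endpoint + 4 s`; the ±4 s
  exclusion is read as symmetric. A postictal amplitude increase clips
  PSI to exactly 0%.
* **COH** averages Welch magnitude-squared coherence (256-sample Hanning
  sub-windows, 50% overlap) over 0.7–25 Hz — the union of the analysis
  bands — and maximizes over 10 s windows sliding by one segment.

Missing values are returned as per-index reason codes, never exceptions,
and batch tables tabulate the reasons — the missing-value accounting is
part of the method's output, because short postictal recordings and
brief seizures are routine in practice.

## Synthetic simulator

`generate_record()` produces two-channel records with four phases:
a mixed-frequency baseline (α-dominant with θ/δ components, random
phases), a saturating square-wave stimulation artifact, a spike-wave
ictal phase (slow wave at `spike_freq`, default 3.5 Hz, plus a
Gaussian-windowed 15 Hz transient per cycle) under a rise–decay
amplitude envelope, and a postictal phase equal to the baseline
morphology scaled by `suppression_ratio`, plus additive Gaussian sensor
noise (SD 1 µV). Channel 2 is a coupling-weighted mixture of channel 1
and an independent realisation.

Amplitude parameters are calibrated in mean-absolute-amplitude terms:
each phase's waveform is normalised to unit mean |x| before scaling.
The envelope rises to `ictal_amp` (default 150 µV against a 20 µV
baseline), decays quadratically, and holds a flat tail at baseline
amplitude over the final 12 s of the seizure — exactly the exclusion
zone plus PSI's late-ictal reference zone. By construction the expected
computed PSI is (1 − suppression_ratio) × 100, which is what the
parameter-recovery tests check (small biases remain from sensor noise
and from reference windows overlapping the decay when the grid is
unfavourably aligned; both are within a few percentage points). Ground
truth: onset = stimulation end (+ optional latency), endpoint = onset +
`ictal_s`.

What the simulator does **not** emulate: muscle and movement artifact,
electrode failures, non-stationary baselines, drug-dependent ictal
morphology, asymmetric or focal seizures, and device-specific
preprocessing. Passing tests therefore demonstrate that the machinery is
correct and internally consistent — endpoint recovery within one window,
PSI parameter recovery, index scaling laws — not that classification
accuracy on clinical EEG will match the synthetic figures. On real data
the feature filters and grids should be revisited against an expert-
labelled sample.

## Numerical choices and problem sizes

* All windows and comparisons use a 1 ns tolerance (`1e-9` s) where grid
  times are compared, because 1.28 s is not exactly representable in
  binary floating point.
* Undersampling, splitting, fold assignment, simulator draws and model
  fits all derive from explicit integer seeds; two runs of the full
  pipeline with the same seed are bit-identical, which is asserted as a
  test.
* EDF output quantizes to the 16-bit grid spanned by each channel's
  amplitude ceiling rounded up to 4 significant digits, so the header
  text and the digitisation use identical ranges and round-trips stay
  within one quantization step. The stimulation marker travels as an
  `STIM_END` annotation in an EDF+ annotations signal.
* Test and example problem sizes are chosen for fast, deterministic
  runs: training sets of 12–40 simulated records (roughly 450–1500
  windows), 100-record endpoint-recovery batches, and 50-record PSI
  sweeps per suppression ratio. These sizes give stable medians and
  means for window-level quantities while keeping the whole suite quick
  to run.

## Known limitations

* The classifier operates per window with no temporal smoothing other
  than the run-length rules; a sequence model could use context.
* Per-patient (grouped) cross-validation is not implemented; windows are
  pooled, so reported synthetic accuracies should not be read as
  patient-generalisation estimates.
* Only the final endpoint of a stimulation is annotated; multi-seizure
  episode parsing is out of scope.
* ICC computation is complete-case (listwise); correlations use pairwise
  deletion.
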