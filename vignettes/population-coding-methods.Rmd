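---
title: "Population coding of odor and place: methods and design notes"
author: "odorplace maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population coding of odor and place: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorplace)
```

# Scope

`odorplace` analyses odor and place information in segmented one-photon
calcium-imaging recordings of the kind collected with head-mounted
miniendoscopes in olfactory cortical areas (piriform cortex, lateral
entorhinal cortex). It covers the full population-coding workflow
downstream of cell segmentation: trial-tensor preprocessing, single-cell
response metrics, trial-by-trial population-vector similarity,
time-resolved odor decoding, and maximum-correlation position decoding on
a linear track. A synthetic-data generator with known ground truth stands
in for raw recordings, so every stage can be validated end to end.

# The data model

The pipeline input is a cells x frames fluorescence matrix at 20 Hz
(`CellTraces`, a thin `SummarizedExperiment`), a behavioural event table
(one row per trial: odor onset frame, stimulus, odor-port side, reward
frame), and — for track sessions — a frame-aligned trajectory (position
in cm, signed velocity, running direction, traversal index).

Two session designs are supported:

* **Head-fixed**: 6 trials x 4 stimuli (three odorants + clean air),
  30 s trials (10 s pre-stimulus, 2 s odor, 18 s post) with 30 s
  inter-trial intervals, stimuli in block-balanced pseudorandom order.
* **Freely moving**: a 100 cm linear track with an odor port at each end;
  48 trials = 12 per stimulus, 6 per port, triggered by nose pokes; the
  analysed trial window is 1 s pre / 2 s odor / 1 s post.

`extractTrials()` cuts these windows into the central 4-D **trial
tensor** `(cells x time x trials x stimuli)` with time 0 at odor onset.

# Preprocessing

Order of operations: smooth, extract, baseline-subtract, z-score — each a
deliberate choice:

* **Smoothing**: five-frame sliding average. We use a *centered* window
  with shrunken edges rather than a causal one: a causal window would
  delay every trace by two frames and bias decoding latencies late.
* **Baseline**: per cell and trial, the mean over the final 1 s (20
  frames) before odor onset is subtracted, even when the pre-stimulus
  phase is longer (head-fixed: 10 s).
* **z-scoring**: each cell is divided by a single scalar — the standard
  deviation of its baseline-subtracted values pooled over *all* frames,
  trials and stimuli. Pooling over all frames (rather than baseline
  frames only) is the more literal reading of normalising by "the
  standard deviation of all trials and odors"; the baseline-only variant
  is available via `normalizeTensor(sdScope = "baseline")`. Cells with
  zero pooled sd are degenerate and are excluded (and recorded in the
  tensor's `excludedCells`).

A consequence worth knowing: because the pooled sd includes the response
frames themselves, strongly responsive cells have their z-scores slightly
compressed. The synthetic generator's `responseAmplitude` is calibrated
net of smoothing but *gross* of this compression, so a planted amplitude
of 3 z is recovered at roughly 2.4 z by `responseMagnitude()`; the exact
attenuation is computable from the kernel by direct integration and the
test suite checks recovery against that expectation.

# Single-cell metrics

A (cell, trial, stimulus) is **activated** when its normalized signal
exceeds 3x the sd of its own 1 s trial baseline for at least 500 ms (10
consecutive frames at 20 Hz) inside the 2 s odor window. The threshold sd
is trial-local so slow drift does not leak into the criterion; cell-trials
with zero baseline sd are indeterminate and counted, never guessed.

* `pctResponsive()`: per stimulus, the average over trials of the
  fraction of activated cells.
* `responseMagnitude()`: mean z over the odor window, averaged over
  activated cell-trials.
* `responseDuration()`: total time above threshold in runs of >= 15
  frames (750 ms), searched over the whole trial since responses can
  outlast the stimulus. When several runs qualify in one trial their
  durations are *summed* (the total supra-threshold time); a
  `rule = "longest"` switch keeps only the longest run.

# Similarity analysis

Single-trial population vectors are per-cell means over the 2 s odor
window (a 5 s variant is supported). `correlationMatrix()` computes
Pearson r between all trial pairs across cells; zero-variance vectors
propagate as `NA`, excluded from every summary rather than imputed.
`sameVsDifferent()` contrasts mean correlation within same-label pairs
against across-label pairs, with two safeguards: the diagonal never
enters (self-correlation would inflate "same"), and the odor-port
contrast uses *within-stimulus* pairs only (same odor / same port vs
same odor / different port), so odor identity cannot masquerade as
spatial context. Clean-air trials are analysable as their own stimulus.
Cross-session pseudopopulations are pooled by stimulus and
within-stimulus trial index — sessions have independent pseudorandom
schedules, so this index is the only common alignment key.

Group-level contrasts operate on per-session (per-mouse) summary values
via a Mann-Whitney rank-sum test with exact enumeration for combined
n <= 12 (valid under ties), the relevant regime for cohort comparisons.

# Odor decoding

`decodeOdors()` classifies stimulus identity from the three odorant
classes (air excluded) with a linear support vector machine under
leave-one-trial-out cross-validation, sliding a 250 ms window frame by
frame. Choices the method text leaves open, fixed here:

* Multiclass scheme: one-vs-one linear classifiers with vote
  aggregation (libsvm via `e1071`), regularization constant 1, no
  feature rescaling beyond the pipeline z-scores. Vote ties resolve to
  the lowest class index, deterministically.
* Window positions lie fully inside the trial and are timestamped at
  the window start; the overall accuracy is the mean over windows fully
  inside the 2 s odor interval.
* The binomial significance series tests, per window, the probability
  of k or more correct classifications out of n decoded trials at
  chance 1/3 (`binomialUpperTail()`, log-space summation; exact against
  an arbitrary-precision oracle to 1e-12). n is the number of decoded
  trials of the design at hand: 18 head-fixed, 36 freely moving. The
  p-series is reported uncorrected for multiple comparisons, matching
  standard practice for these descriptive time courses — a documented
  limitation.
* `ensembleSizeScan()` repeats the decoding on random cell subsets in
  steps of five, 100 iterations per size, drawing a fresh uniform subset
  without replacement at every size and iteration from a seeded
  generator, and histograms the maximum odor-window accuracy per size.

A caveat that matters when interpreting chance levels: leave-one-out
cross-validation is *pessimistically biased at chance*. The held-out
trial's class is always under-represented in training (11 vs 12), and
with many more cells than trials the classifier is in the separable
regime where majority classes claim more decision volume. On pure-noise
data (36 trials x 100 cells) the expected shuffled-label accuracy is
about 31% rather than 33.3%, and correlated trial structure (context
responses shared across trials, as real recordings also show) lowers it
by another one to two points. Shuffle controls should therefore be
compared against an empirical permutation distribution, not against the
nominal 1/3.

# Spatial analyses

The track is divided into 24 half-open bins of 100/24 cm (bin indices
0-based; position 100 closes the last bin). Only *running epochs* enter:
speed strictly above 2 cm/s and outside the two bins at each end, leaving
20 decodable interior bins. Population rate maps are per-bin means of the
normalized traces (no deconvolution — all analyses stay on the calcium
signal), split by running direction and by odd/even traversal.

Because the task is a shuttle run, global traversal order alternates
directions; the cross-validation unit is therefore the k-th traversal
*within* a direction. `decodePosition()` decodes each frame as the bin
whose template population vector correlates best with the frame's
activity (ties to the lowest bin; correlations within 1e-12 count as
tied so floating-point noise cannot flip a tie; undefined correlations
always lose). Same-direction decoding trains on even traversals to
decode odd ones and vice versa; cross-direction decoding trains on one
direction and tests on the other, scored either against the allocentric
position or against its mirror image (the matched trajectory phase).
Squared errors are reported in bin^2 with a cm^2 conversion available via
the bin width.

The **differentiation index** summarizes how strongly the two running
directions' spatial codes differ:

$$\mathrm{DI} = \frac{c_\mathrm{same} - c_\mathrm{diff}}{c_\mathrm{same} + c_\mathrm{diff}}$$

The operands are deliberately both split-half quantities:
\(c_\mathrm{same}\) correlates odd- and even-traversal maps of the same
direction at matched positions; \(c_\mathrm{diff}\) correlates
odd-traversal maps of one direction with even-traversal maps of the other
at the *mirror-symmetric* position (matched trajectory phase). Using
cross-parity halves for both keeps their noise floors comparable; a
full-data \(c_\mathrm{diff}\) against a split-half \(c_\mathrm{same}\)
would bias the index. With this definition a fully direction-specific
code scores near 1 and a trajectory-phase (mirror-symmetric) code scores
near 0 — the qualitative ordering observed between entorhinal and
piriform populations. An allocentric variant of the cross-direction
matching is exposed via `phaseReference = "allocentric"`. The index is
refused (NA with a warning) when \(c_\mathrm{same} + c_\mathrm{diff}
\le 0\).

# The synthetic generator

`simulateHeadFixed()` and `simulateTrack()` emulate the two designs with
configurable ground truth (`synthConfig()`), for parameter-recovery
testing:

* **Calcium kernel**: causal single exponential, unit peak, default
  decay 1.5 s (slow-indicator GCaMP7s-like dynamics), implemented as an
  exact first-order recursive filter.
* **Odor/port responses**: a 2 s boxcar drive convolved with the kernel,
  rescaled to unit mean over the odor window; the injected raw amplitude
  is `responseAmplitude x noiseSd / sqrt(5)` so that after the standard
  five-frame smoothing and z-scoring the mean odor-window response is
  approximately `responseAmplitude` z-units. At the default amplitude
  3 z / noise 1, per-trial detection sensitivity is ~0.85 and the
  false-positive rate ~0.4% — planted responsive fractions are
  recoverable within a few percentage points.
* **Place cells**: Gaussian fields (sd 8 cm), drive evaluated along the
  trajectory and convolved with the kernel, peak-calibrated at running
  speed. Per cell, a Bernoulli draw with probability
  `directionSpecificity` decides between independent fields per
  direction and mirror-symmetric fields about the track midpoint (same
  trajectory phase in both directions).
* **Trajectory**: constant-speed traversals (15 cm/s) with 5 s port
  dwells; each arrival triggers a trial; stimuli follow block-balanced
  shuffles per port ("pseudorandom" is not further specified in the
  emulated design; block balance is our choice).
* **Noise**: i.i.d. Gaussian per frame (default sd 1) plus an optional
  slow drift, off by default — keeps analytic expectations tractable.
* **Tuned fractions** default to 15% odor-tuned per odorant, 10%
  port-tuned, 30% place-tuned — typical of olfactory cortical
  populations of a few hundred cells.

What the generator does *not* emulate: motion artifacts, neuropil
contamination, cross-session registration error, spike-to-fluorescence
nonlinearity, behavioural variability in running speed, or overdispersed
noise. Passing recovery tests on these synthetics therefore validates the
*analysis logic*, not robustness to every artifact of real miniscope
data.

# Numerical conventions and problem sizes

* All randomness flows through explicit seeds; the same configuration
  and seed reproduce a dataset bit for bit.
* Exact small-sample statistics: rank-sum p-values switch from exact
  enumeration to the tie-corrected normal approximation above combined
  n = 12 (recorded in the result's method label); the binomial tail is
  summed in log space.
* Boundary conventions: activation needs strictly more than threshold;
  the running gate needs speed strictly above 2 cm/s; spatial bins are
  half-open with the last closed; 500 ms = 10 frames and 750 ms = 15
  frames exactly at 20 Hz.
* The validation suite runs the study-scale configurations (100-cell
  populations, 20-seed averages for recovery statistics, 10 paired seeds
  for the direction-specificity contrast); unit tests use smaller
  populations chosen to exercise the same code paths quickly.

# A minimal worked example

```{r example, eval = FALSE}
cfg <- synthConfig(nCells = 100, design = "freely_moving", seed = 1)
sim <- simulateTrack(cfg)
tensor <- buildTensor(sim$traces, sim$events)

pctResponsive(detectActivated(tensor))
decodeOdors(tensor, timeRange = c(0, 2))

nt <- normalizeTraces(sim$traces)
decodePosition(nt, sim$trajectory, mode = "same_direction")
directionCorrelation(nt, sim$trajectory)
```

# Known limitations

* The pooled-sd z-score compresses large responses (see Preprocessing);
  comparisons of magnitudes across datasets assume similar response
  sparsity.
* Leave-one-out decoding is conservatively biased at chance (see Odor
  decoding); significance against chance should rely on the binomial or
  permutation machinery, not on a nominal 33.3% line.
* The time-resolved p-series is uncorrected for multiple comparisons.
* Position decoding assumes a stable spatial code across a session; no
  drift correction is applied.
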