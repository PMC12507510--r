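# odorplace

Population-coding analysis of odor and place information in segmented
calcium-imaging recordings, for labs studying how olfactory cortical areas
(piriform cortex, lateral entorhinal cortex) represent odor identity and
spatial context in head-fixed and freely-moving mice.

The package takes the standard outputs of miniscope cell segmentation — a
cells × frames fluorescence matrix at 20 Hz, a behavioural event table, and
(for linear-track sessions) a frame-aligned trajectory — and implements the
complete downstream workflow:

* **Preprocessing** — five-frame smoothing, 1 s baseline subtraction,
  pooled-sd z-scoring, assembly into the 4-D trial tensor
  (cells × time × trials × stimuli) with time 0 at odor onset.
* **Single-cell metrics** — responsive cells (signal > 3 × baseline sd for
  ≥ 500 ms in the 2 s odor window), response magnitude, response duration.
* **Population similarity** — Pearson correlations between single-trial
  population vectors; same-vs-different odor and same-vs-different port
  contrasts with exact small-sample rank-sum tests.
* **Odor decoding** — leave-one-trial-out linear SVM over a 250 ms sliding
  window: time-resolved accuracy, confusion matrices, a binomial
  significance series
  `P(X ≥ k), X ~ Binomial(n, 1/3)` per time point, and ensemble-size
  subsampling (accuracy-vs-size probability maps).
* **Place decoding** — 24-bin maximum-correlation position decoder on a
  100 cm track (running epochs only: speed > 2 cm/s, end bins excluded),
  odd/even traversal cross-validation, cross-direction decoding with
  allocentric or mirrored scoring, and the differentiation index
  `DI = (c_same − c_diff) / (c_same + c_diff)` separating
  direction-specific from trajectory-phase spatial codes.
* **Synthetic data** — generators for both session designs with known
  ground truth (odor-, port- and place-tuned cells, exponential calcium
  kernel, configurable noise), so every stage is testable without raw
  recordings.

See `vignettes/population-coding-methods.Rmd` for the full model
description, parameter defaults, and design rationale.

## Worked example

```r
library(odorplace)

cfg <- synthConfig(nCells = 100, design = "freely_moving", seed = 1)
sim <- simulateTrack(cfg)                      # traces, events, trajectory, truth
tensor <- buildTensor(sim$traces, sim$events)  # smooth -> extract -> z-score
tensor
#> TrialTensor: 100 cells x 80 frames x 12 trials x 4 stimuli
#>   window: 1 s pre / 2 s odor / 1 s post at 20 Hz
#>   stimuli: odorA, odorC, odorB, air
#>   normalized: TRUE

round(pctResponsive(detectActivated(tensor)), 2)
#> odorA odorC odorB   air
#> 15.00 15.17 15.50  4.42
```

With 15 % of cells planted as responsive per odorant, the detector recovers
15.0–15.5 % per odorant; the 4.4 % on clean air comes from port-context
cells that respond at the odor port regardless of stimulus.

```r
res <- decodeOdors(tensor, timeRange = c(0, 2))
res
#> DecodingResult: 36 window positions (250 ms window), 36 trials
#>   odor-window accuracy: 0.978 (chance 0.333)
#>   time points with p < 0.05: 36 / 36
```

Odor identity is decoded nearly perfectly from the tuned population at all
36 window positions inside the 2 s odor interval (binomial test against
chance 1/3, n = 36 trials).

```r
nt <- normalizeTraces(sim$traces)
decodePosition(nt, sim$trajectory, mode = "same_direction")
#> PositionDecodingResult (same_direction, allocentric scoring): 5217 frames decoded
#>   mse 2.007 bin^2 (34.8 cm^2), median |error| 1.00 bins

directionCorrelation(nt, sim$trajectory)
#> DirectionCorrelationStructure: 24 bins x 2 directions
#>   c_same 0.795, c_diff 0.531, differentiation index 0.199
```

Position on the track is recovered to a median error of one 4.2 cm bin
from odd/even split-half templates. The differentiation index of 0.20
reflects the generator's default 50 % direction-specific place cells;
fully direction-specific populations score near 0.7 and trajectory-phase
(mirror-symmetric) populations near 0.

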