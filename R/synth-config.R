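#' Configure a synthetic calcium-imaging session
#'
#' Builds a validated [SynthConfig-class]. The defaults encode the emulated
#' study conditions: 20 Hz imaging; four stimuli (three odorants plus clean
#' air); six trials per stimulus head-fixed or twelve (six per odor port)
#' freely moving; and a 100 cm linear track traversed at 15 cm/s for the
#' freely-moving design. Tuned fractions default to values typical of
#' olfactory cortical recordings (15 % odor-tuned per odorant, 10 %
#' port/context-tuned, 30 % place-tuned).
#'
#' `responseAmplitude` is calibrated so that, after the standard
#' preprocessing (five-frame smoothing, baseline subtraction, pooled-sd
#' z-scoring), a tuned cell's mean response over the 2 s odor window is
#' approximately `responseAmplitude` z-units.
#'
#' @param nCells number of cells.
#' @param frameRate imaging rate in Hz.
#' @param design `"head_fixed"` or `"freely_moving"`.
#' @param nStimuli number of stimuli; the last is always clean air.
#' @param trialsPerStimulus trials per stimulus; defaults to 6 (head-fixed)
#'   or 12 (freely moving). Must be even for the freely-moving design.
#' @param fracOdorTuned fraction of cells tuned to each odorant.
#' @param fracPortTuned fraction of cells tuned to one odor port.
#' @param fracPlaceTuned fraction of cells with place fields.
#' @param directionSpecificity probability that a place cell has independent
#'   fields in the two running directions (otherwise its fields are
#'   mirror-symmetric about the track midpoint, i.e. trajectory-phase locked).
#' @param responseAmplitude mean odor-window response in z-units.
#' @param kernelDecayS exponential calcium-kernel decay constant in seconds.
#' @param noiseSd per-frame Gaussian noise sd (raw units).
#' @param placeFieldSdCm Gaussian place-field width (sd) in cm.
#' @param runSpeedCmS running speed on the track in cm/s.
#' @param baselineDriftSd sd of a slow additive baseline drift; 0 disables.
#' @param seed integer RNG seed; the same config and seed always yield a
#'   bit-identical dataset.
#' @return a [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(nCells = 50, seed = 7)
#' cfg
#' @export
synthConfig <- function(nCells = 100, frameRate = 20,
                        design = c("head_fixed", "freely_moving"),
                        nStimuli = 4, trialsPerStimulus = NULL,
                        fracOdorTuned = 0.15, fracPortTuned = 0.1,
                        fracPlaceTuned = 0.3, directionSpecificity = 0.5,
                        responseAmplitude = 3, kernelDecayS = 1.5,
                        noiseSd = 1, placeFieldSdCm = 8, runSpeedCmS = 15,
                        baselineDriftSd = 0, seed = 1) {
  design <- match.arg(design)
  if (is.null(trialsPerStimulus))
    trialsPerStimulus <- if (design == "head_fixed") 6 else 12
  methods::new("SynthConfig", nCells = nCells, frameRate = frameRate,
               design = design, nStimuli = nStimuli,
               trialsPerStimulus = trialsPerStimulus,
               fracOdorTuned = fracOdorTuned, fracPortTuned = fracPortTuned,
               fracPlaceTuned = fracPlaceTuned,
               directionSpecificity = directionSpecificity,
               responseAmplitude = responseAmplitude,
               kernelDecayS = kernelDecayS, noiseSd = noiseSd,
               placeFieldSdCm = placeFieldSdCm, runSpeedCmS = runSpeedCmS,
               baselineDriftSd = baselineDriftSd, seed = seed)
}

# Stimulus labels for a config; the last stimulus is always clean air.
.stimulusLabels <- function(config) {
  k <- config@nStimuli
  if (k == 4) c("odorA", "odorB", "odorC", "air")
  else c(sprintf("odor%s", LETTERS[seq_len(k - 1)]), "air")
}

# Odorant labels (air excluded).
.odorLabels <- function(config) {
  labs <- .stimulusLabels(config)
  labs[-length(labs)]
}
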