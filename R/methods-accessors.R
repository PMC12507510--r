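#' @rdname accessors
#' @export
setMethod("frameRate", "CellTraces",
          function(x) S4Vectors::metadata(x)$frame_rate_hz)

#' @rdname accessors
#' @export
setMethod("frameRate", "TrialTensor", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("frameRate", "TrackTrajectory", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("traceMatrix", "CellTraces",
          function(x) SummarizedExperiment::assay(x, "fluo"))

#' @rdname accessors
#' @export
setMethod("cellIds", "CellTraces", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("cellIds", "TrialTensor", function(x) x@cellIds)

#' @rdname accessors
#' @export
setMethod("nCells", "CellTraces", function(x) nrow(x))

#' @rdname accessors
#' @export
setMethod("nCells", "TrialTensor", function(x) dim(x@values)[1L])

#' @rdname accessors
#' @export
setMethod("tensorValues", "TrialTensor", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("timeAxis", "TrialTensor", function(x) x@timeAxis)

#' @rdname accessors
#' @export
setMethod("trialMeta", "TrialTensor", function(x) x@trialMeta)

#' @rdname accessors
#' @export
setMethod("trialMeta", "TrialVectorSet", function(x) x@trialMeta)

#' @rdname accessors
#' @export
setMethod("trialMeta", "SimilarityMatrix", function(x) x@trialMeta)

#' @rdname accessors
#' @export
setMethod("stimuli", "TrialTensor", function(x) x@stimuli)

#' @rdname accessors
#' @export
setMethod("accuracySeries", "DecodingResult", function(x) x@accuracySeries)

#' @rdname accessors
#' @export
setMethod("overallAccuracy", "DecodingResult", function(x) x@overallAccuracy)

#' @rdname accessors
#' @export
setMethod("confusionMatrix", "DecodingResult", function(x) x@confusion)

#' @rdname accessors
#' @export
setMethod("pSeries", "DecodingResult", function(x) x@pSeries)

#' @rdname accessors
#' @export
setMethod("rateMatrix", "PopulationRateMap", function(x) x@rates)

#' @rdname accessors
#' @export
setMethod("differentiationIndex", "DirectionCorrelationStructure",
          function(x) x@differentiationIndex)

#' @rdname accessors
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("TrialTensor: %d cells x %d frames x %d trials x %d stimuli\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  window: %g s pre / %g s odor / %g s post at %g Hz\n",
              object@windowSpec[1], object@windowSpec[2],
              object@windowSpec[3], object@frameRate))
  cat(sprintf("  stimuli: %s\n", paste(object@stimuli, collapse = ", ")))
  cat(sprintf("  normalized: %s", object@normalized))
  if (length(object@excludedCells))
    cat(sprintf(" (%d degenerate cells excluded)",
                length(object@excludedCells)))
  cat("\n")
})

setMethod("show", "TrackTrajectory", function(object) {
  cat(sprintf(
    "TrackTrajectory: %d frames at %g Hz on a %g cm track, %d traversals\n",
    length(object@positionCm), object@frameRate, object@trackCm,
    max(object@traversalIndex)))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf("SynthConfig: %s design, %d cells at %g Hz, %d x %d trials\n",
              object@design, object@nCells, object@frameRate,
              object@trialsPerStimulus, object@nStimuli))
  cat(sprintf(
    "  tuned fractions: odor %.2f, port %.2f, place %.2f (dir. spec. %.2f)\n",
    object@fracOdorTuned, object@fracPortTuned, object@fracPlaceTuned,
    object@directionSpecificity))
  cat(sprintf("  amplitude %g z, kernel decay %g s, noise sd %g, seed %d\n",
              object@responseAmplitude, object@kernelDecayS, object@noiseSd,
              as.integer(object@seed)))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf(
    "DecodingResult: %d window positions (%.0f ms window), %d trials\n",
    length(object@accuracySeries), object@windowS * 1000, object@nTrials))
  cat(sprintf("  odor-window accuracy: %.3f (chance %.3f)\n",
              object@overallAccuracy, object@chance))
  nsig <- sum(object@pSeries < 0.05)
  cat(sprintf("  time points with p < 0.05: %d / %d\n", nsig,
              length(object@pSeries)))
})

setMethod("show", "EnsembleSizeResult", function(object) {
  cat(sprintf(
    "EnsembleSizeResult: sizes %s cells, %d iterations per size\n",
    paste(range(object@sizes), collapse = "-"), nrow(object@maxAccuracy)))
})

setMethod("show", "PopulationRateMap", function(object) {
  cat(sprintf(
    "PopulationRateMap: %d bins x %d cells, %s traversals, %s direction (%d usable bins)\n",
    nrow(object@rates), ncol(object@rates), object@parity, object@direction,
    sum(object@usableBins)))
})

setMethod("show", "PositionDecodingResult", function(object) {
  cat(sprintf(
    "PositionDecodingResult (%s, %s scoring): %d frames decoded\n",
    object@mode, object@scoring, length(object@decodedBin)))
  cat(sprintf("  mse %.3f bin^2 (%.1f cm^2), median |error| %.2f bins\n",
              object@mse, object@mse * object@binWidthCm^2,
              object@medianAbsError))
})

setMethod("show", "DirectionCorrelationStructure", function(object) {
  cat(sprintf(
    "DirectionCorrelationStructure: %d bins x 2 directions\n", object@nBins))
  cat(sprintf("  c_same %.3f, c_diff %.3f, differentiation index %.3f\n",
              object@cSame, object@cDiff, object@differentiationIndex))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s (%s-tailed): statistic %.4g, p = %.4g (n = %s)\n",
              object@method, object@tails, object@statistic, object@pValue,
              paste(object@nPerGroup, collapse = ", ")))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d x %d trials, ordered by %s\n",
              nrow(object@values), ncol(object@values), object@ordering))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d odor-tuned sets, %d port sets, %d place cells\n",
    length(object@odorTuned), length(object@portTuned),
    nrow(object@placeCells)))
})
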