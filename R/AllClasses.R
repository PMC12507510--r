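#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats cor sd rnorm rbinom runif filter t.test pnorm quantile median setNames
#' @importFrom utils read.csv write.csv combn head tail
#' @importFrom graphics hist
NULL

#' CellTraces: segmented fluorescence traces
#'
#' Container for a session of segmented single-cell calcium traces, stored as
#' a cells x frames matrix inside a [SummarizedExperiment::SummarizedExperiment].
#' Rows are cells, columns are frames. Session-level metadata (frame rate in
#' Hz, session design, region label, mouse id) live in `metadata()`.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`.
#' @seealso [cellTraces()], [frameRate()], [traceMatrix()]
#' @export
setClass("CellTraces", contains = "SummarizedExperiment")

setValidity("CellTraces", function(object) {
  msg <- NULL
  if (!"fluo" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'fluo' is missing")
  else {
    m <- SummarizedExperiment::assay(object, "fluo")
    if (anyNA(m)) msg <- c(msg, "traces contain missing values")
  }
  fr <- S4Vectors::metadata(object)$frame_rate_hz
  if (is.null(fr) || !is.numeric(fr) || length(fr) != 1L || fr <= 0)
    msg <- c(msg, "metadata frame_rate_hz must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CellTraces object
#'
#' @param values numeric matrix, cells in rows and frames in columns.
#' @param frameRate acquisition rate in Hz (miniscope standard: 20).
#' @param cellIds character vector of cell identifiers; defaults to
#'   `cell_001 ...`.
#' @param design `"head_fixed"` or `"freely_moving"`.
#' @param region region label, e.g. `"PCx"` or `"LEC"` (free text allowed).
#' @param mouse mouse/session identifier.
#' @param normalized logical flag recording whether the traces have already
#'   been smoothed and z-scored (see [normalizeTraces()]).
#' @return a [CellTraces-class] object.
#' @export
cellTraces <- function(values, frameRate = 20, cellIds = NULL,
                       design = c("head_fixed", "freely_moving"),
                       region = NA_character_, mouse = NA_character_,
                       normalized = FALSE) {
  design <- match.arg(design)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(cellIds)) {
    cellIds <- rownames(values)
    if (is.null(cellIds))
      cellIds <- sprintf("cell_%03d", seq_len(nrow(values)))
  }
  stopifnot(length(cellIds) == nrow(values))
  rownames(values) <- cellIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fluo = values),
    metadata = list(frame_rate_hz = frameRate, design = design,
                    region = region, mouse = mouse, normalized = normalized))
  methods::new("CellTraces", se)
}

#' TrialTensor: trial-aligned 4-D activity dataset
#'
#' The central 4-D dataset of the pipeline: `values[cell, time, trial,
#' stimulus]`, with time relative to odor onset. Raw tensors hold fluorescence
#' in acquisition units; after [normalizeTensor()] values are z-units and
#' `normalized` is `TRUE`.
#'
#' @slot values 4-D numeric array (cells x time x trials-per-stimulus x stimuli).
#' @slot timeAxis numeric, seconds relative to odor onset (frame-aligned).
#' @slot windowSpec named numeric of length 3: `pre_s`, `odor_s`, `post_s`.
#' @slot frameRate acquisition rate in Hz.
#' @slot stimuli character, stimulus labels (4th dimension).
#' @slot cellIds character, cell identifiers (1st dimension).
#' @slot trialMeta data.frame with one row per (stimulus, trial): columns
#'   `stimulus`, `trial`, `port`, `onset_frame`.
#' @slot normalized logical.
#' @slot excludedCells character, ids of degenerate (zero-variance) cells
#'   dropped during normalization.
#' @export
setClass("TrialTensor", representation(
  values = "array", timeAxis = "numeric", windowSpec = "numeric",
  frameRate = "numeric", stimuli = "character", cellIds = "character",
  trialMeta = "data.frame", normalized = "logical",
  excludedCells = "character"))

setValidity("TrialTensor", function(object) {
  msg <- NULL
  d <- dim(object@values)
  if (length(d) != 4L) return("values must be a 4-D array")
  if (length(object@timeAxis) != d[2L])
    msg <- c(msg, "timeAxis length must match the time dimension")
  if (length(object@stimuli) != d[4L])
    msg <- c(msg, "stimuli labels must match the stimulus dimension")
  if (length(object@cellIds) != d[1L])
    msg <- c(msg, "cellIds must match the cell dimension")
  if (length(object@windowSpec) != 3L)
    msg <- c(msg, "windowSpec must have pre_s, odor_s, post_s")
  if (nrow(object@trialMeta) != d[3L] * d[4L])
    msg <- c(msg, "trialMeta must have one row per trial x stimulus")
  if (is.null(msg)) TRUE else msg
})

#' TrackTrajectory: frame-aligned linear-track trajectory
#'
#' Position, velocity, running direction and traversal index per imaging
#' frame on a linear track.
#'
#' @slot positionCm numeric, position along the track in cm.
#' @slot velocityCmS numeric, signed velocity in cm/s (positive = rightward).
#' @slot direction factor with levels rightward/leftward/stationary.
#' @slot traversalIndex integer, which end-to-end run each frame belongs to
#'   (non-decreasing; dwell frames keep the index of the preceding run).
#' @slot frameRate acquisition rate in Hz.
#' @slot trackCm track length in cm.
#' @export
setClass("TrackTrajectory", representation(
  positionCm = "numeric", velocityCmS = "numeric", direction = "factor",
  traversalIndex = "integer", frameRate = "numeric", trackCm = "numeric"))

setValidity("TrackTrajectory", function(object) {
  msg <- NULL
  n <- length(object@positionCm)
  if (length(object@velocityCmS) != n || length(object@direction) != n ||
      length(object@traversalIndex) != n)
    msg <- c(msg, "all per-frame series must have equal length")
  if (any(object@positionCm < -1e-9 | object@positionCm > object@trackCm + 1e-9))
    msg <- c(msg, "positions outside [0, trackCm]")
  if (!all(levels(object@direction) %in%
           c("rightward", "leftward", "stationary")))
    msg <- c(msg, "direction levels must be rightward/leftward/stationary")
  if (is.unsorted(object@traversalIndex))
    msg <- c(msg, "traversalIndex must be non-decreasing")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TrackTrajectory
#'
#' @param positionCm,velocityCmS,direction,traversalIndex per-frame series;
#'   see [TrackTrajectory-class].
#' @param frameRate acquisition rate in Hz.
#' @param trackCm track length in cm.
#' @export
trackTrajectory <- function(positionCm, velocityCmS, direction,
                            traversalIndex, frameRate = 20, trackCm = 100) {
  methods::new("TrackTrajectory",
    positionCm = as.numeric(positionCm),
    velocityCmS = as.numeric(velocityCmS),
    direction = factor(as.character(direction),
                       levels = c("rightward", "leftward", "stationary")),
    traversalIndex = as.integer(traversalIndex),
    frameRate = frameRate, trackCm = trackCm)
}

#' SynthConfig: synthetic-session configuration
#'
#' Parameters of the synthetic calcium-imaging session generator. Defaults
#' follow the study designs the generator emulates: 20 Hz imaging; head-fixed
#' sessions of 6 trials x 4 stimuli with 30 s trials (10 s pre / 2 s odor /
#' 18 s post) and 30 s inter-trial intervals; freely-moving sessions of 48
#' trials (12 per stimulus, 6 per odor port) with 4 s trial windows (1 s pre /
#' 2 s odor / 1 s post) on a 100 cm track.
#'
#' @slot nCells number of cells.
#' @slot frameRate imaging rate, Hz.
#' @slot design `"head_fixed"` or `"freely_moving"`.
#' @slot nStimuli number of stimuli (default 4: three odorants plus clean air).
#' @slot trialsPerStimulus trials per stimulus (6 head-fixed, 12 freely moving).
#' @slot fracOdorTuned fraction of cells tuned to each odorant.
#' @slot fracPortTuned fraction of cells tuned to an odor port (context).
#' @slot fracPlaceTuned fraction of cells with place fields.
#' @slot directionSpecificity probability that a place cell is
#'   direction-specific (0 = all fields mirror-symmetric / trajectory-phase,
#'   1 = all fields direction-specific).
#' @slot responseAmplitude mean odor-window response of tuned cells, z-units
#'   (as measured after the standard preprocessing).
#' @slot kernelDecayS calcium-kernel exponential decay constant, s.
#' @slot noiseSd per-frame Gaussian noise sd, raw units.
#' @slot placeFieldSdCm Gaussian place-field width (sd), cm.
#' @slot runSpeedCmS running speed on the track, cm/s.
#' @slot baselineDriftSd sd of an optional slow baseline drift (0 = off).
#' @slot seed RNG seed.
#' @export
setClass("SynthConfig", representation(
  nCells = "numeric", frameRate = "numeric", design = "character",
  nStimuli = "numeric", trialsPerStimulus = "numeric",
  fracOdorTuned = "numeric", fracPortTuned = "numeric",
  fracPlaceTuned = "numeric", directionSpecificity = "numeric",
  responseAmplitude = "numeric", kernelDecayS = "numeric",
  noiseSd = "numeric", placeFieldSdCm = "numeric", runSpeedCmS = "numeric",
  baselineDriftSd = "numeric", seed = "numeric"))

setValidity("SynthConfig", function(object) {
  msg <- NULL
  chkProp <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      sprintf("'%s' must be a proportion in [0, 1]", name)
    else NULL
  }
  if (object@nCells < 1) msg <- c(msg, "'nCells' must be >= 1")
  if (object@frameRate <= 0) msg <- c(msg, "'frameRate' must be > 0")
  if (!object@design %in% c("head_fixed", "freely_moving"))
    msg <- c(msg, "'design' must be head_fixed or freely_moving")
  msg <- c(msg, chkProp(object@fracOdorTuned, "fracOdorTuned"),
           chkProp(object@fracPortTuned, "fracPortTuned"),
           chkProp(object@fracPlaceTuned, "fracPlaceTuned"),
           chkProp(object@directionSpecificity, "directionSpecificity"))
  if (object@kernelDecayS <= 0) msg <- c(msg, "'kernelDecayS' must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@design == "freely_moving" &&
      object@trialsPerStimulus %% 2 != 0)
    msg <- c(msg,
      "'trialsPerStimulus' must be even in the freely_moving design (equal split across the two ports)")
  if (is.null(msg)) TRUE else msg
})

#' GroundTruth: planted tuning of a synthetic session
#'
#' @slot odorTuned named list: cell indices tuned to each odorant.
#' @slot portTuned named list: cell indices tuned to each port.
#' @slot placeCells data.frame: `cell`, `center_right_cm`, `center_left_cm`,
#'   `direction_specific`.
#' @slot config the generating [SynthConfig-class].
#' @export
setClass("GroundTruth", representation(
  odorTuned = "list", portTuned = "list", placeCells = "data.frame",
  config = "SynthConfig"))

#' TrialVectorSet: single-trial population response vectors
#'
#' One population vector per trial: each entry is a cell's mean z-scored
#' activity over the odor-exposure window.
#'
#' @slot vectors numeric matrix, trials x cells.
#' @slot trialMeta data.frame with `stimulus`, `trial`, `port` per row.
#' @slot windowS averaging window length, s (from odor onset).
#' @export
setClass("TrialVectorSet", representation(
  vectors = "matrix", trialMeta = "data.frame", windowS = "numeric"))

#' SimilarityMatrix: trial-by-trial Pearson correlation matrix
#'
#' @slot values symmetric trials x trials matrix of Pearson r (diagonal 1);
#'   rows/columns of zero-variance trial vectors are `NA`.
#' @slot trialMeta data.frame aligned with the rows.
#' @slot ordering character, how trials are sorted ("stimulus" or "port").
#' @export
setClass("SimilarityMatrix", representation(
  values = "matrix", trialMeta = "data.frame", ordering = "character"))

#' DecodingResult: time-resolved odor decoding
#'
#' @slot accuracySeries proportion correct per sliding-window position.
#' @slot timePoints window start time (s, relative to odor onset) per position.
#' @slot confusion stimulus x stimulus matrix of classification proportions
#'   (rows = true label, pooled over the odor window; rows sum to 1).
#' @slot pSeries upper-tail binomial p-value per position.
#' @slot windowS sliding-window length, s.
#' @slot overallAccuracy mean accuracy over windows inside the odor window.
#' @slot nTrials number of decoded trials.
#' @slot chance chance level (1/number of classes).
#' @slot odorWindow numeric length 2, odor window bounds in s.
#' @export
setClass("DecodingResult", representation(
  accuracySeries = "numeric", timePoints = "numeric", confusion = "matrix",
  pSeries = "numeric", windowS = "numeric", overallAccuracy = "numeric",
  nTrials = "numeric", chance = "numeric", odorWindow = "numeric"))

setValidity("DecodingResult", function(object) {
  msg <- NULL
  if (any(object@accuracySeries < 0 | object@accuracySeries > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (any(object@pSeries <= 0 | object@pSeries > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(object@accuracySeries) != length(object@timePoints))
    msg <- c(msg, "accuracySeries and timePoints must align")
  if (is.null(msg)) TRUE else msg
})

#' EnsembleSizeResult: decoding accuracy vs ensemble size
#'
#' @slot sizes ensemble sizes (cells), stepping by `step`.
#' @slot maxAccuracy matrix iterations x sizes: max odor-window decoding
#'   accuracy of each random ensemble.
#' @slot probabilityMap matrix accuracy-bins x sizes: per-size normalized
#'   histogram of max accuracy (columns sum to 1).
#' @slot breaks histogram bin edges.
#' @export
setClass("EnsembleSizeResult", representation(
  sizes = "numeric", maxAccuracy = "matrix", probabilityMap = "matrix",
  breaks = "numeric"))

#' PopulationRateMap: spatially binned population activity
#'
#' @slot rates bins x cells matrix: mean normalized activity per spatial bin
#'   (NA where unoccupied).
#' @slot occupancy frames per bin (after the running-epoch gate).
#' @slot direction `"rightward"` or `"leftward"`.
#' @slot parity traversal subset: `"odd"`, `"even"` or `"all"`.
#' @slot nBins number of spatial bins over the track.
#' @slot trackCm track length, cm.
#' @slot usableBins logical per bin: interior bin with occupancy > 0.
#' @export
setClass("PopulationRateMap", representation(
  rates = "matrix", occupancy = "numeric", direction = "character",
  parity = "character", nBins = "numeric", trackCm = "numeric",
  usableBins = "logical"))

#' PositionDecodingResult: maximum-correlation position decoding
#'
#' @slot decodedBin decoded spatial bin per decoded frame (0-based).
#' @slot trueBin true (or mirrored, depending on `scoring`) bin per frame.
#' @slot squaredErrors squared bin error per frame.
#' @slot mse mean squared error, bin^2.
#' @slot medianAbsError median absolute error, bins.
#' @slot mode `"same_direction"` or `"cross_direction"`.
#' @slot scoring `"allocentric"` or `"mirrored"`.
#' @slot nBins,binWidthCm binning geometry.
#' @export
setClass("PositionDecodingResult", representation(
  decodedBin = "integer", trueBin = "integer", squaredErrors = "numeric",
  mse = "numeric", medianAbsError = "numeric", mode = "character",
  scoring = "character", nBins = "numeric", binWidthCm = "numeric"))

#' DirectionCorrelationStructure: position x direction correlation analysis
#'
#' Pairwise Pearson correlations between population activity vectors at every
#' (spatial bin, running direction) combination, plus the differentiation
#' index contrasting within-direction and cross-direction (trajectory-phase
#' matched) similarity.
#'
#' @slot corr (2*nBins) x (2*nBins) correlation matrix, rightward bins first.
#' @slot cSame mean within-direction, cross-parity, matched-position r.
#' @slot cDiff mean cross-direction, cross-parity, mirror-position r.
#' @slot differentiationIndex (cSame - cDiff) / (cSame + cDiff); NA when the
#'   denominator is <= 0.
#' @slot nBins number of spatial bins.
#' @export
setClass("DirectionCorrelationStructure", representation(
  corr = "matrix", cSame = "numeric", cDiff = "numeric",
  differentiationIndex = "numeric", nBins = "numeric"))

#' TestResult: outcome of a statistical test
#'
#' @slot statistic test statistic.
#' @slot pValue p-value in (0, 1].
#' @slot method method label.
#' @slot tails `"one"` or `"two"`.
#' @slot nPerGroup group sizes.
#' @export
setClass("TestResult", representation(
  statistic = "numeric", pValue = "numeric", method = "character",
  tails = "character", nPerGroup = "numeric"))

setValidity("TestResult", function(object) {
  if (length(object@pValue) == 1L &&
      (is.na(object@pValue) || (object@pValue > 0 && object@pValue <= 1)))
    TRUE
  else "pValue must be a single value in (0, 1]"
})
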