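#' Simulate a head-fixed odor-exposure session
#'
#' Generates a synthetic head-fixed session with known ground truth:
#' `trialsPerStimulus` trials of each stimulus in a block-balanced
#' pseudorandom order, each trial 30 s long (10 s pre-stimulus, 2 s odor,
#' 18 s post-stimulus) followed by a 30 s inter-trial interval. Cells tuned
#' to an odorant emit a kernel-convolved transient during the 2 s odor
#' window of that odorant's trials; all cells carry i.i.d. Gaussian frame
#' noise (plus optional slow drift).
#'
#' @param config a [SynthConfig-class] with `design = "head_fixed"`.
#' @return a list with elements `traces` ([CellTraces-class]), `events`
#'   (data.frame: `trial`, `onset_frame`, `stimulus`, `port`,
#'   `reward_frame`) and `truth` ([GroundTruth-class]).
#' @examples
#' sim <- simulateHeadFixed(synthConfig(nCells = 20, seed = 1))
#' dim(traceMatrix(sim$traces))
#' @export
simulateHeadFixed <- function(config) {
  .stopIfNot(methods::is(config, "SynthConfig"),
             "configuration error: 'config' must be a SynthConfig")
  .stopIfNot(config@design == "head_fixed",
             "configuration error: 'design' must be head_fixed")
  methods::validObject(config)
  set.seed(as.integer(config@seed))

  fr <- config@frameRate
  preS <- 10; odorS <- 2; postS <- 18; itiS <- 30
  trialLen <- as.integer((preS + odorS + postS) * fr)
  slotLen <- trialLen + as.integer(itiS * fr)
  stimLabels <- .stimulusLabels(config)
  odors <- .odorLabels(config)
  nTrials <- as.integer(config@nStimuli * config@trialsPerStimulus)
  totalFrames <- nTrials * slotLen
  nCells <- as.integer(config@nCells)

  schedule <- .balancedSchedule(stimLabels, config@trialsPerStimulus)
  onsets <- (seq_len(nTrials) - 1L) * slotLen + as.integer(preS * fr) + 1L

  odorTuned <- stats::setNames(lapply(odors, function(s)
    sort(sample.int(nCells, round(config@fracOdorTuned * nCells)))), odors)

  amp <- .rawAmplitude(config) * .odorTemplateScale(config)
  odorFrames <- as.integer(odorS * fr)

  values <- matrix(stats::rnorm(nCells * totalFrames, 0, config@noiseSd),
                   nrow = nCells)
  if (config@baselineDriftSd > 0)
    for (c in seq_len(nCells))
      values[c, ] <- values[c, ] + .baselineDrift(totalFrames,
                                                  config@baselineDriftSd)

  # one drive per odorant, shared by all cells tuned to it
  for (s in odors) {
    cellsS <- odorTuned[[s]]
    if (!length(cellsS)) next
    drive <- numeric(totalFrames)
    for (i in which(schedule == s))
      drive[onsets[i]:(onsets[i] + odorFrames - 1L)] <- 1
    resp <- amp * calciumConvolve(drive, config@kernelDecayS, fr)
    values[cellsS, ] <- values[cellsS, , drop = FALSE] +
      matrix(resp, nrow = length(cellsS), ncol = totalFrames, byrow = TRUE)
  }

  traces <- cellTraces(values, frameRate = fr, design = "head_fixed",
                       mouse = sprintf("sim_%d", as.integer(config@seed)))
  events <- data.frame(trial = seq_len(nTrials), onset_frame = onsets,
                       stimulus = schedule, port = "none",
                       reward_frame = NA_integer_)
  truth <- methods::new("GroundTruth", odorTuned = odorTuned,
                        portTuned = list(),
                        placeCells = data.frame(), config = config)
  list(traces = traces, events = events, truth = truth)
}
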