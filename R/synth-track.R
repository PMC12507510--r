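#' Simulate a freely-moving linear-track session
#'
#' Generates a synthetic linear-track session: the animal shuttles between
#' two odor ports at the ends of a 100 cm track at constant speed, and each
#' port arrival triggers a trial (1 s pre-stimulus dwell, 2 s odor, 1 s
#' post). Stimuli follow a block-balanced pseudorandom schedule per port, so
#' each odorant occurs equally often at the two ports. Three tuning regimes
#' can be planted: odorant-tuned cells (respond during their odorant's 2 s
#' window at either port), port-tuned cells (respond at one port regardless
#' of stimulus), and place cells with Gaussian spatial fields convolved with
#' the calcium kernel. Depending on `directionSpecificity`, a place cell
#' either has independent fields per running direction or mirror-symmetric
#' fields about the track midpoint (same trajectory phase in both
#' directions).
#'
#' @param config a [SynthConfig-class] with `design = "freely_moving"`.
#' @param trackCm track length in cm.
#' @return a list with elements `traces` ([CellTraces-class]), `events`
#'   (data.frame with `trial`, `onset_frame`, `stimulus`, `port`,
#'   `reward_frame`), `trajectory` ([TrackTrajectory-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' sim <- simulateTrack(synthConfig(nCells = 20, design = "freely_moving",
#'                                  seed = 1))
#' sim$trajectory
#' @export
simulateTrack <- function(config, trackCm = 100) {
  .stopIfNot(methods::is(config, "SynthConfig"),
             "configuration error: 'config' must be a SynthConfig")
  .stopIfNot(config@design == "freely_moving",
             "configuration error: 'design' must be freely_moving")
  methods::validObject(config)
  set.seed(as.integer(config@seed))

  fr <- config@frameRate
  dwellFrames <- as.integer(5 * fr)          # port dwell covering the trial
  preFrames <- as.integer(1 * fr)            # odor onset 1 s into the dwell
  odorFrames <- as.integer(2 * fr)
  stimLabels <- .stimulusLabels(config)
  odors <- .odorLabels(config)
  nTrials <- as.integer(config@nStimuli * config@trialsPerStimulus)
  nCells <- as.integer(config@nCells)
  v <- config@runSpeedCmS
  step <- v / fr
  runPos <- c(seq(step, trackCm - step, by = step), trackCm)  # one traversal

  # per-port block-balanced schedules; ports alternate left, right, ...
  perPort <- as.integer(config@trialsPerStimulus / 2)
  schedLeft <- .balancedSchedule(stimLabels, perPort)
  schedRight <- .balancedSchedule(stimLabels, perPort)

  pos <- numeric(0); vel <- numeric(0); dirv <- character(0)
  trav <- integer(0)
  onsets <- integer(nTrials); ports <- character(nTrials)
  stimulus <- character(nTrials)
  iL <- 0L; iR <- 0L
  for (t in seq_len(nTrials)) {
    atLeft <- t %% 2L == 1L
    portPos <- if (atLeft) 0 else trackCm
    ports[t] <- if (atLeft) "left" else "right"
    if (atLeft) { iL <- iL + 1L; stimulus[t] <- schedLeft[iL] }
    else        { iR <- iR + 1L; stimulus[t] <- schedRight[iR] }
    onsets[t] <- length(pos) + preFrames + 1L
    pos <- c(pos, rep(portPos, dwellFrames))
    vel <- c(vel, rep(0, dwellFrames))
    dirv <- c(dirv, rep("stationary", dwellFrames))
    trav <- c(trav, rep(t - 1L, dwellFrames))
    if (t < nTrials) {  # traverse to the other port
      p <- if (atLeft) runPos else trackCm - runPos
      dp <- diff(c(portPos, p))
      pos <- c(pos, p)
      vel <- c(vel, dp * fr)
      dirv <- c(dirv, rep(if (atLeft) "rightward" else "leftward", length(p)))
      trav <- c(trav, rep(t, length(p)))
    }
  }
  totalFrames <- length(pos)
  trajectory <- trackTrajectory(pos, vel, dirv, trav, frameRate = fr,
                                trackCm = trackCm)

  # --- tuning assignments -------------------------------------------------
  odorTuned <- stats::setNames(lapply(odors, function(s)
    sort(sample.int(nCells, round(config@fracOdorTuned * nCells)))), odors)
  nPort <- round(config@fracPortTuned * nCells)
  portCells <- sample.int(nCells, nPort)
  portTuned <- list(left = sort(portCells[seq_len(nPort %/% 2)]),
                    right = sort(portCells[setdiff(seq_len(nPort),
                                                   seq_len(nPort %/% 2))]))
  nPlace <- round(config@fracPlaceTuned * nCells)
  placeIdx <- sort(sample.int(nCells, nPlace))
  dirSpecific <- stats::runif(nPlace) < config@directionSpecificity
  centerR <- stats::runif(nPlace, 0.1 * trackCm, 0.9 * trackCm)
  centerL <- ifelse(dirSpecific,
                    stats::runif(nPlace, 0.1 * trackCm, 0.9 * trackCm),
                    trackCm - centerR)
  placeCells <- data.frame(cell = placeIdx, center_right_cm = centerR,
                           center_left_cm = centerL,
                           direction_specific = dirSpecific)

  # --- trace synthesis ----------------------------------------------------
  ampOdor <- .rawAmplitude(config) * .odorTemplateScale(config)
  values <- matrix(stats::rnorm(nCells * totalFrames, 0, config@noiseSd),
                   nrow = nCells)
  if (config@baselineDriftSd > 0)
    for (c in seq_len(nCells))
      values[c, ] <- values[c, ] + .baselineDrift(totalFrames,
                                                  config@baselineDriftSd)

  addBoxcarResponse <- function(cells, trialIdx) {
    if (!length(cells) || !length(trialIdx)) return()
    drive <- numeric(totalFrames)
    for (i in trialIdx)
      drive[onsets[i]:(onsets[i] + odorFrames - 1L)] <- 1
    resp <- ampOdor * calciumConvolve(drive, config@kernelDecayS, fr)
    values[cells, ] <<- values[cells, , drop = FALSE] +
      matrix(resp, nrow = length(cells), ncol = totalFrames, byrow = TRUE)
  }
  for (s in odors) addBoxcarResponse(odorTuned[[s]], which(stimulus == s))
  addBoxcarResponse(portTuned$left, which(ports == "left"))
  addBoxcarResponse(portTuned$right, which(ports == "right"))

  if (nPlace > 0) {
    # normalize a reference field passage (at running speed) to unit peak
    sig <- config@placeFieldSdCm
    refDrive <- exp(-(seq(-5 * sig, 5 * sig, by = step))^2 / (2 * sig^2))
    refPeak <- max(calciumConvolve(refDrive, config@kernelDecayS, fr))
    ampPlace <- .rawAmplitude(config) / refPeak
    right <- dirv == "rightward"; left <- dirv == "leftward"
    for (j in seq_len(nPlace)) {
      drive <- numeric(totalFrames)
      drive[right] <- exp(-(pos[right] - centerR[j])^2 / (2 * sig^2))
      drive[left] <- exp(-(pos[left] - centerL[j])^2 / (2 * sig^2))
      values[placeIdx[j], ] <- values[placeIdx[j], ] +
        ampPlace * calciumConvolve(drive, config@kernelDecayS, fr)
    }
  }

  traces <- cellTraces(values, frameRate = fr, design = "freely_moving",
                       mouse = sprintf("sim_%d", as.integer(config@seed)))
  events <- data.frame(trial = seq_len(nTrials), onset_frame = onsets,
                       stimulus = stimulus, port = ports,
                       reward_frame = onsets + as.integer(3 * fr))
  truth <- methods::new("GroundTruth", odorTuned = odorTuned,
                        portTuned = portTuned, placeCells = placeCells,
                        config = config)
  list(traces = traces, events = events, trajectory = trajectory,
       truth = truth)
}

#' Simulate a cohort of independent sessions
#'
#' Convenience wrapper generating several independent synthetic sessions
#' ("mice") from one base configuration, so per-mouse averaging in the
#' statistics can be exercised. Session `i` uses seed `seed + i - 1`.
#'
#' @param config base [SynthConfig-class].
#' @param nMice number of independent sessions.
#' @return list of simulation results (see [simulateHeadFixed()] /
#'   [simulateTrack()]).
#' @export
simulateCohort <- function(config, nMice = 3) {
  lapply(seq_len(nMice), function(i) {
    cfg <- config
    cfg@seed <- config@seed + i - 1
    if (cfg@design == "head_fixed") simulateHeadFixed(cfg)
    else simulateTrack(cfg)
  })
}
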