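#' Smooth calcium traces with a sliding-window average
#'
#' Replaces every trace by its centered moving average (default five frames,
#' the standard for 20 Hz miniscope data). Edge frames use shrunken windows,
#' so the output has the same length and no phase lag.
#'
#' @param traces a [CellTraces-class] object.
#' @param windowFrames odd window length in frames (>= 1); `1` is a no-op.
#' @return a smoothed [CellTraces-class].
#' @export
smoothTraces <- function(traces, windowFrames = 5) {
  .stopIfNot(methods::is(traces, "CellTraces"),
             "'traces' must be a CellTraces object")
  .stopIfNot(length(windowFrames) == 1L && windowFrames >= 1 &&
               windowFrames %% 2 == 1,
             "configuration error: 'windowFrames' must be odd and >= 1")
  m <- traceMatrix(traces)
  if (windowFrames > 1)
    m <- t(apply(m, 1L, .movingAverage, w = as.integer(windowFrames)))
  md <- S4Vectors::metadata(traces)
  cellTraces(m, frameRate = md$frame_rate_hz, cellIds = rownames(traces),
             design = md$design, region = md$region, mouse = md$mouse,
             normalized = isTRUE(md$normalized))
}

#' Extract trial-aligned windows into a raw 4-D tensor
#'
#' Cuts a window around every odor onset and stacks the slices into a raw
#' [TrialTensor-class] `(cells x time x trials x stimuli)`. Time 0 of the
#' tensor's axis is the odor-onset frame. Trials are grouped by stimulus,
#' preserving chronological order within each stimulus; odor-port labels are
#' carried as trial metadata.
#'
#' @param traces a [CellTraces-class].
#' @param events event table (data.frame) with columns `onset_frame`,
#'   `stimulus` and optionally `port` and `trial`; onsets must be strictly
#'   increasing.
#' @param preS,odorS,postS window phases in seconds. Defaults follow the
#'   head-fixed design (10 / 2 / 18 s); freely-moving sessions use 1 / 2 / 1.
#' @return a raw (non-normalized) [TrialTensor-class].
#' @export
extractTrials <- function(traces, events, preS = 10, odorS = 2, postS = 18) {
  .stopIfNot(methods::is(traces, "CellTraces"),
             "'traces' must be a CellTraces object")
  .checkEventTable(events)
  fr <- frameRate(traces)
  m <- traceMatrix(traces)
  nFrames <- ncol(m)
  preF <- as.integer(round(preS * fr))
  lenF <- as.integer(round((preS + odorS + postS) * fr))
  stimLabels <- unique(events$stimulus)
  counts <- table(events$stimulus)
  if (length(unique(counts)) != 1L)
    stop("unequal trial counts per stimulus: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  nPer <- as.integer(counts[1L])

  vals <- array(NA_real_, dim = c(nrow(m), lenF, nPer, length(stimLabels)))
  meta <- vector("list", length(stimLabels))
  for (si in seq_along(stimLabels)) {
    rows <- which(events$stimulus == stimLabels[si])  # chronological
    for (ti in seq_along(rows)) {
      onset <- events$onset_frame[rows[ti]]
      lo <- onset - preF
      hi <- lo + lenF - 1L
      if (lo < 1L || hi > nFrames)
        stop(sprintf(
          "trial %s (stimulus %s, onset frame %d): window [%d, %d] outside recording of %d frames",
          rows[ti], stimLabels[si], onset, lo, hi, nFrames))
      vals[, , ti, si] <- m[, lo:hi]
    }
    meta[[si]] <- data.frame(
      stimulus = stimLabels[si], trial = seq_along(rows),
      port = if ("port" %in% names(events)) events$port[rows] else "none",
      onset_frame = events$onset_frame[rows])
  }
  methods::new("TrialTensor", values = vals,
               timeAxis = (seq_len(lenF) - 1L - preF) / fr,
               windowSpec = c(pre_s = preS, odor_s = odorS, post_s = postS),
               frameRate = fr, stimuli = as.character(stimLabels),
               cellIds = rownames(m), trialMeta = do.call(rbind, meta),
               normalized = FALSE, excludedCells = character(0))
}

#' Normalize a trial tensor to baseline-referenced z-units
#'
#' Two-step normalization of a raw [TrialTensor-class]: (1) for every cell
#' and trial, the mean over the final 1 s of the pre-stimulus window is
#' subtracted (baseline referencing); (2) each cell's signals are divided by
#' a single scalar, the standard deviation of that cell's baseline-subtracted
#' values pooled over all frames, trials and stimuli (the default) or pooled
#' over baseline frames only (`sdScope = "baseline"`). Cells with zero
#' pooled sd are degenerate; they are excluded from the tensor and recorded
#' in `excludedCells`.
#'
#' @param tensor a raw [TrialTensor-class] with `pre_s >= 1`.
#' @param sdScope which frames enter the pooled sd: `"all"` (every frame of
#'   every trial and stimulus) or `"baseline"` (the 1 s baselines only).
#' @return a normalized [TrialTensor-class].
#' @export
normalizeTensor <- function(tensor, sdScope = c("all", "baseline")) {
  .stopIfNot(methods::is(tensor, "TrialTensor"),
             "'tensor' must be a TrialTensor")
  sdScope <- match.arg(sdScope)
  .stopIfNot(tensor@windowSpec[["pre_s"]] >= 1,
             "insufficient baseline: pre-stimulus window must be >= 1 s")
  v <- tensor@values
  d <- dim(v)
  base <- .baselineFrames(tensor)
  # per (cell, trial, stimulus) baseline mean
  bmean <- apply(v[, base, , , drop = FALSE], c(1, 3, 4), mean)
  v <- v - aperm(array(bmean, dim = c(d[1], d[3], d[4], d[2])),
                 c(1, 4, 2, 3))
  pool <- if (sdScope == "all") v else v[, base, , , drop = FALSE]
  sds <- apply(pool, 1L, stats::sd)
  keep <- sds > 0
  excluded <- tensor@cellIds[!keep]
  if (length(excluded))
    message(length(excluded), " degenerate cell(s) with zero pooled sd excluded: ",
            paste(excluded, collapse = ", "))
  v <- v[keep, , , , drop = FALSE] / sds[keep]
  methods::new("TrialTensor", values = v, timeAxis = tensor@timeAxis,
               windowSpec = tensor@windowSpec, frameRate = tensor@frameRate,
               stimuli = tensor@stimuli, cellIds = tensor@cellIds[keep],
               trialMeta = tensor@trialMeta, normalized = TRUE,
               excludedCells = as.character(excluded))
}

#' Build a normalized trial tensor in one call
#'
#' Convenience wrapper chaining [smoothTraces()], [extractTrials()] and
#' [normalizeTensor()] with the window defaults of the given design.
#'
#' @param traces a [CellTraces-class].
#' @param events event table (see [extractTrials()]).
#' @param design trial-window design; defaults to the traces' metadata.
#' @param smoothWindow smoothing window in frames.
#' @param ... passed to [normalizeTensor()].
#' @return a normalized [TrialTensor-class].
#' @export
buildTensor <- function(traces, events, design = NULL, smoothWindow = 5,
                        ...) {
  if (is.null(design)) design <- S4Vectors::metadata(traces)$design
  design <- match.arg(design, c("head_fixed", "freely_moving"))
  w <- if (design == "head_fixed") c(10, 2, 18) else c(1, 2, 1)
  sm <- smoothTraces(traces, smoothWindow)
  normalizeTensor(extractTrials(sm, events, w[1], w[2], w[3]), ...)
}

#' Smooth and z-score a full-session trace matrix
#'
#' Session-level normalization used by the spatial analyses (which operate
#' on the continuous recording rather than trial windows): traces are
#' smoothed with the standard five-frame window, then each cell is z-scored
#' against its whole-session mean and sd.
#'
#' @param traces a [CellTraces-class].
#' @param smoothWindow smoothing window in frames.
#' @return a normalized [CellTraces-class] (`metadata(x)$normalized` TRUE).
#' @export
normalizeTraces <- function(traces, smoothWindow = 5) {
  sm <- smoothTraces(traces, smoothWindow)
  m <- traceMatrix(sm)
  mu <- rowMeans(m)
  sds <- apply(m, 1L, stats::sd)
  sds[sds == 0] <- 1  # constant cells stay flat at zero
  m <- (m - mu) / sds
  md <- S4Vectors::metadata(traces)
  cellTraces(m, frameRate = md$frame_rate_hz, cellIds = rownames(traces),
             design = md$design, region = md$region, mouse = md$mouse,
             normalized = TRUE)
}

# frames of the final 1 s of the pre-stimulus window (time in [-1, 0))
.baselineFrames <- function(tensor) {
  which(tensor@timeAxis >= -1 & tensor@timeAxis < 0)
}

# frames of the odor window [0, odorS)
.odorFrames <- function(tensor, odorS = tensor@windowSpec[["odor_s"]]) {
  which(tensor@timeAxis >= 0 & tensor@timeAxis < odorS)
}

.checkEventTable <- function(events) {
  .stopIfNot(is.data.frame(events), "'events' must be a data.frame")
  for (col in c("onset_frame", "stimulus"))
    if (!col %in% names(events))
      stop(sprintf("event table schema error: missing column '%s'", col))
  .stopIfNot(!is.unsorted(events$onset_frame, strictly = TRUE),
             "event onsets must be strictly increasing")
  invisible(TRUE)
}
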