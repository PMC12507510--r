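#' Detect odor-activated cell-trials
#'
#' Marks a (cell, trial, stimulus) as activated when, within the 2 s odor
#' window, the normalized signal exceeds `kSd` times the standard deviation
#' of that cell-trial's 1 s pre-stimulus baseline for at least `minDurS`
#' consecutively (10 frames at 20 Hz by default). Cell-trials with zero
#' baseline sd are indeterminate: they are reported inactive and counted in
#' the `indeterminate` attribute.
#'
#' @param tensor a normalized [TrialTensor-class].
#' @param kSd threshold multiplier on the baseline sd.
#' @param minDurS minimum supra-threshold duration in seconds.
#' @return logical array `(cells x trials x stimuli)` with attribute
#'   `indeterminate` (count of zero-baseline-sd cell-trials).
#' @export
detectActivated <- function(tensor, kSd = 3, minDurS = 0.5) {
  .stopIfNot(methods::is(tensor, "TrialTensor") && tensor@normalized,
             "'tensor' must be a normalized TrialTensor")
  fr <- tensor@frameRate
  minFrames <- as.integer(ceiling(minDurS * fr))
  base <- .baselineFrames(tensor)
  odorW <- .odorFrames(tensor)
  v <- tensor@values
  d <- dim(v)
  mask <- array(FALSE, dim = d[c(1, 3, 4)],
                dimnames = list(tensor@cellIds, NULL, tensor@stimuli))
  indeterminate <- 0L
  for (s in seq_len(d[4])) for (tr in seq_len(d[3])) {
    bsd <- apply(v[, base, tr, s, drop = FALSE], 1L, stats::sd)
    zero <- bsd == 0
    indeterminate <- indeterminate + sum(zero)
    thr <- kSd * bsd
    w <- matrix(v[, odorW, tr, s], nrow = d[1])
    for (c in which(!zero))
      mask[c, tr, s] <- .hasRun(w[c, ] > thr[c], minFrames)
  }
  attr(mask, "indeterminate") <- indeterminate
  attr(mask, "kSd") <- kSd
  mask
}

#' Percentage of responsive cells
#'
#' For each stimulus, the average over trials of the fraction of activated
#' cells, in percent; the dataset-level value is the mean over stimuli.
#'
#' @param mask activation mask from [detectActivated()].
#' @param per `"stimulus"` for one value per stimulus, `"dataset"` for the
#'   mean over stimuli.
#' @return named numeric vector of percentages (or a single percentage).
#' @export
pctResponsive <- function(mask, per = c("stimulus", "dataset")) {
  per <- match.arg(per)
  .stopIfNot(is.array(mask) && length(dim(mask)) == 3L && length(mask) > 0,
             "'mask' must be a non-empty cells x trials x stimuli array")
  perStim <- apply(mask, 3L, function(m) mean(colMeans(m)) * 100)
  if (per == "stimulus") perStim else mean(perStim)
}

#' Mean odor-response magnitude of activated cells
#'
#' Averages the z-scored signal over the 2 s odor window for every activated
#' (cell, trial, stimulus) and summarizes across all of them, mirroring the
#' per-mouse magnitude statistic of responsive-cell analyses.
#'
#' @param tensor a normalized [TrialTensor-class].
#' @param mask activation mask from [detectActivated()].
#' @return list with `values` (data.frame: cell, trial, stimulus, magnitude
#'   per activated cell-trial) and `mean` (their average; `NA` if no cell is
#'   activated, with zero rows in `values`).
#' @export
responseMagnitude <- function(tensor, mask) {
  .stopIfNot(methods::is(tensor, "TrialTensor") && tensor@normalized,
             "'tensor' must be a normalized TrialTensor")
  odorW <- .odorFrames(tensor)
  winMean <- apply(tensor@values[, odorW, , , drop = FALSE], c(1, 3, 4), mean)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(list(values = data.frame(cell = character(0), trial = integer(0),
                                    stimulus = character(0),
                                    magnitude = numeric(0)),
                mean = NA_real_))
  vals <- winMean[idx]
  list(values = data.frame(cell = tensor@cellIds[idx[, 1L]],
                           trial = idx[, 2L],
                           stimulus = tensor@stimuli[idx[, 3L]],
                           magnitude = vals),
       mean = mean(vals))
}

#' Supra-threshold response durations
#'
#' For every (cell, trial, stimulus), measures how long the cell's activity
#' stays above `kSd` times its trial-baseline sd in runs of at least
#' `minFrames` consecutive frames (15 frames = 750 ms at 20 Hz), searching
#' the whole trial (responses can outlast the stimulus). Multiple qualifying
#' runs are summed by default (`rule = "sum"`); `rule = "longest"` keeps only
#' the longest run.
#'
#' @param tensor a normalized [TrialTensor-class].
#' @param kSd threshold multiplier on the baseline sd.
#' @param minFrames minimum run length in frames.
#' @param rule `"sum"` or `"longest"`.
#' @return data.frame with columns `cell`, `trial`, `stimulus`,
#'   `duration_s`, one row per qualifying cell-trial (duration > 0 only).
#' @export
responseDuration <- function(tensor, kSd = 3, minFrames = 15,
                             rule = c("sum", "longest")) {
  .stopIfNot(methods::is(tensor, "TrialTensor") && tensor@normalized,
             "'tensor' must be a normalized TrialTensor")
  rule <- match.arg(rule)
  fr <- tensor@frameRate
  base <- .baselineFrames(tensor)
  v <- tensor@values
  d <- dim(v)
  out <- list()
  for (s in seq_len(d[4])) for (tr in seq_len(d[3])) {
    bsd <- apply(v[, base, tr, s, drop = FALSE], 1L, stats::sd)
    for (c in seq_len(d[1])) {
      if (bsd[c] == 0) next
      runs <- .trueRunLengths(v[c, , tr, s] > kSd * bsd[c])
      runs <- runs[runs >= minFrames]
      if (!length(runs)) next
      durF <- if (rule == "sum") sum(runs) else max(runs)
      out[[length(out) + 1L]] <- data.frame(
        cell = tensor@cellIds[c], trial = tr, stimulus = tensor@stimuli[s],
        duration_s = durF / fr)
    }
  }
  if (!length(out))
    return(data.frame(cell = character(0), trial = integer(0),
                      stimulus = character(0), duration_s = numeric(0)))
  do.call(rbind, out)
}
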