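#' Sliding-window feature matrices for decoding
#'
#' For every window position (moving frame by frame across the trial), a
#' `(trials x cells)` matrix of within-window mean responses. Only the
#' odorant trials enter (clean air is excluded from classification). Window
#' positions lie fully inside the trial; each is timestamped at its start
#' frame.
#'
#' @param tensor a normalized [TrialTensor-class].
#' @param windowS sliding-window length in seconds (250 ms default).
#' @param stimuli stimuli to decode; defaults to all non-air stimuli.
#' @param timeRange optional numeric length-2: restrict window start times
#'   to `[timeRange[1], timeRange[2]]` seconds (windows must still fit).
#' @return list with `features` (list of trials x cells matrices),
#'   `timePoints` (window start times, s), `labels` (factor, stimulus per
#'   trial) and `ports` (port label per trial).
#' @export
windowFeatures <- function(tensor, windowS = 0.25, stimuli = NULL,
                           timeRange = NULL) {
  .stopIfNot(methods::is(tensor, "TrialTensor") && tensor@normalized,
             "'tensor' must be a normalized TrialTensor")
  fr <- tensor@frameRate
  wlen <- as.integer(round(windowS * fr))
  nT <- length(tensor@timeAxis)
  .stopIfNot(wlen >= 1 && wlen <= nT,
             "'windowS' must fit within the trial")
  if (is.null(stimuli)) stimuli <- setdiff(tensor@stimuli, "air")
  si <- match(stimuli, tensor@stimuli)
  .stopIfNot(!anyNA(si), "unknown stimulus in 'stimuli'")
  d <- dim(tensor@values)
  starts <- seq_len(nT - wlen + 1L)
  if (!is.null(timeRange)) {
    tAx <- tensor@timeAxis
    starts <- starts[tAx[starts] >= timeRange[1] &
                       tAx[starts] + wlen / fr <= timeRange[2] + 1e-9]
    .stopIfNot(length(starts) > 0, "'timeRange' leaves no window position")
  }
  v <- tensor@values[, , , si, drop = FALSE]
  labels <- factor(rep(stimuli, each = d[3]), levels = stimuli)
  meta <- tensor@trialMeta
  ports <- unlist(lapply(stimuli, function(s)
    meta$port[meta$stimulus == s]))
  # cumulative sum over time for fast window means
  cs <- apply(v, c(1, 3, 4), cumsum)           # time x cells x trials x stim
  feat <- lapply(starts, function(st) {
    hi <- st + wlen - 1L
    wm <- if (st == 1L) cs[hi, , , ] else cs[hi, , , ] - cs[st - 1L, , , ]
    wm <- array(wm, dim = c(d[1], d[3], length(si))) / wlen
    t(matrix(wm, nrow = d[1]))                  # (trials*stim) x cells
  })
  list(features = feat, timePoints = tensor@timeAxis[starts],
       labels = labels, ports = ports, windowS = wlen / fr,
       odorWindow = c(0, tensor@windowSpec[["odor_s"]]),
       nTrialsPerClass = d[3])
}

#' Leave-one-trial-out linear-SVM decoding
#'
#' At every sliding-window position, each trial is held out in turn and its
#' stimulus predicted by a linear-kernel support vector machine (one-vs-one
#' multiclass voting, cost 1, no rescaling — the features are already
#' pipeline z-scores) trained on all remaining trials. Returns the
#' time-resolved accuracy, a confusion matrix pooled over the odor window,
#' the upper-tail binomial p-value series against chance, and the overall
#' odor-window accuracy.
#'
#' @param features output of [windowFeatures()].
#' @param labels optional factor overriding the stimulus labels (e.g. a
#'   shuffled permutation for a chance-level control); must keep >= 2 trials
#'   per class.
#' @param chance chance probability; defaults to 1 / number of classes.
#' @param cost SVM regularization constant.
#' @return a [DecodingResult-class].
#' @export
lotoDecode <- function(features, labels = NULL, chance = NULL, cost = 1) {
  .stopIfNot(is.list(features) && !is.null(features$features),
             "'features' must come from windowFeatures()")
  y <- if (is.null(labels)) features$labels else as.factor(labels)
  nTrials <- length(y)
  counts <- table(y)
  if (any(counts < 2))
    stop("leave-one-trial-out undefined: class(es) with a single trial: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  if (is.null(chance)) chance <- 1 / nlevels(y)
  tp <- features$timePoints
  odorW <- features$odorWindow
  nPos <- length(features$features)
  correct <- integer(nPos)
  classes <- levels(y)
  pooled <- matrix(0, nlevels(y), nlevels(y),
                   dimnames = list(true = classes, predicted = classes))
  inOdor <- tp >= odorW[1] &
    tp + features$windowS <= odorW[2] + 1e-9
  for (w in seq_len(nPos)) {
    X <- features$features[[w]]
    pred <- character(nTrials)
    for (i in seq_len(nTrials)) {
      fit <- e1071::svm(X[-i, , drop = FALSE], y[-i], kernel = "linear",
                        cost = cost, scale = FALSE)
      pred[i] <- as.character(predict(fit, X[i, , drop = FALSE]))
    }
    correct[w] <- sum(pred == as.character(y))
    if (inOdor[w])
      pooled <- pooled + table(factor(as.character(y), levels = classes),
                               factor(pred, levels = classes))
  }
  acc <- correct / nTrials
  confusion <- pooled / pmax(rowSums(pooled), 1)
  overall <- if (any(inOdor)) mean(acc[inOdor]) else NA_real_
  methods::new("DecodingResult", accuracySeries = acc, timePoints = tp,
               confusion = unclass(confusion),
               pSeries = binomialUpperTail(correct, nTrials, chance),
               windowS = features$windowS, overallAccuracy = overall,
               nTrials = nTrials, chance = chance, odorWindow = odorW)
}

#' Time-resolved odor decoding from a trial tensor
#'
#' Convenience wrapper: [windowFeatures()] then [lotoDecode()].
#'
#' @param tensor a normalized [TrialTensor-class].
#' @param windowS sliding-window length, s.
#' @param cells optional cell subset (indices) to decode from.
#' @param timeRange optional window-start time range (see
#'   [windowFeatures()]); the default decodes the full trial.
#' @param ... passed to [lotoDecode()].
#' @return a [DecodingResult-class].
#' @export
decodeOdors <- function(tensor, windowS = 0.25, cells = NULL,
                        timeRange = NULL, ...) {
  if (!is.null(cells)) tensor <- .subsetCells(tensor, cells)
  lotoDecode(windowFeatures(tensor, windowS, timeRange = timeRange), ...)
}

#' Binomial p-value series for a decoding time course
#'
#' Upper-tail binomial probability per time point for `k` correct out of
#' `n` decoded trials at chance `p` (see [binomialUpperTail()]).
#'
#' @param correctCounts integer vector of correct classifications per time
#'   point.
#' @param nTrials number of decoded trials.
#' @param chance chance probability.
#' @return numeric vector of p-values with attribute `significant`
#'   (`p < 0.05`).
#' @export
binomialPSeries <- function(correctCounts, nTrials, chance = 1 / 3) {
  p <- binomialUpperTail(correctCounts, nTrials, chance)
  attr(p, "significant") <- p < 0.05
  p
}

#' Decoding accuracy as a function of ensemble size
#'
#' Repeats leave-one-trial-out decoding on randomly drawn cell subsets of
#' increasing size (steps of five cells, fresh uniform draw without
#' replacement at every size and iteration) and records, for each run, the
#' maximum of the time-resolved accuracy within the 2 s odor window. The
#' per-size histogram of maxima, normalized by the number of iterations,
#' gives the probability map displayed as an accuracy-vs-ensemble-size
#' heatmap.
#'
#' @param tensor a normalized [TrialTensor-class].
#' @param step ensemble-size step (default 5 cells).
#' @param iterations random subsets per size (study default 100).
#' @param seed RNG seed for the subset draws.
#' @param windowS sliding-window length, s.
#' @param nBreaks number of histogram bins over [0, 1].
#' @param ... passed to [lotoDecode()].
#' @return an [EnsembleSizeResult-class].
#' @export
ensembleSizeScan <- function(tensor, step = 5, iterations = 100, seed = 1,
                             windowS = 0.25, nBreaks = 20, ...) {
  .stopIfNot(methods::is(tensor, "TrialTensor") && tensor@normalized,
             "'tensor' must be a normalized TrialTensor")
  nc <- nCells(tensor)
  .stopIfNot(step <= nc, "'step' exceeds the number of cells")
  sizes <- seq(step, nc, by = step)
  set.seed(as.integer(seed))
  odorS <- tensor@windowSpec[["odor_s"]]
  maxAcc <- matrix(NA_real_, nrow = iterations, ncol = length(sizes),
                   dimnames = list(NULL, sizes))
  for (it in seq_len(iterations)) {
    for (k in seq_along(sizes)) {
      cells <- sample.int(nc, sizes[k])
      res <- decodeOdors(tensor, windowS = windowS, cells = cells,
                         timeRange = c(0, odorS), ...)
      inOdor <- res@timePoints + res@windowS <= odorS + 1e-9 &
        res@timePoints >= 0
      maxAcc[it, k] <- max(res@accuracySeries[inOdor])
    }
  }
  breaks <- seq(0, 1, length.out = nBreaks + 1L)
  pm <- apply(maxAcc, 2L, function(x)
    graphics::hist(x, breaks = breaks, plot = FALSE)$counts / iterations)
  methods::new("EnsembleSizeResult", sizes = sizes, maxAccuracy = maxAcc,
               probabilityMap = pm, breaks = breaks)
}

# Restrict a tensor to a cell subset (indices or ids).
.subsetCells <- function(tensor, cells) {
  if (is.character(cells)) cells <- match(cells, tensor@cellIds)
  .stopIfNot(!anyNA(cells) && all(cells >= 1 & cells <= nCells(tensor)),
             "invalid cell subset")
  methods::new("TrialTensor",
               values = tensor@values[cells, , , , drop = FALSE],
               timeAxis = tensor@timeAxis, windowSpec = tensor@windowSpec,
               frameRate = tensor@frameRate, stimuli = tensor@stimuli,
               cellIds = tensor@cellIds[cells], trialMeta = tensor@trialMeta,
               normalized = tensor@normalized,
               excludedCells = tensor@excludedCells)
}
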