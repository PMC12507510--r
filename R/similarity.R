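#' Build single-trial population response vectors
#'
#' One vector per trial: each cell's mean z-scored activity over the first
#' `windowS` seconds after odor onset (the 2 s odor-exposure window by
#' default; a 5 s variant is supported for extended-window analyses).
#'
#' @param tensor a normalized [TrialTensor-class].
#' @param windowS averaging window in seconds from odor onset; must lie
#'   within the tensor's time axis.
#' @return a [TrialVectorSet-class]; rows are trials (stimulus-major order),
#'   columns are cells.
#' @export
trialVectors <- function(tensor, windowS = 2) {
  .stopIfNot(methods::is(tensor, "TrialTensor"),
             "'tensor' must be a TrialTensor")
  .stopIfNot(windowS > 0 && windowS <= max(tensor@timeAxis) + 1 / tensor@frameRate,
             "'windowS' outside the tensor time axis")
  w <- .odorFrames(tensor, odorS = windowS)
  vm <- apply(tensor@values[, w, , , drop = FALSE], c(1, 3, 4), mean)
  d <- dim(vm)  # cells x trials x stimuli
  vectors <- t(matrix(vm, nrow = d[1]))  # (trials*stimuli) x cells
  colnames(vectors) <- tensor@cellIds
  methods::new("TrialVectorSet", vectors = vectors,
               trialMeta = tensor@trialMeta, windowS = windowS)
}

#' Pool trial vectors across sessions into a pseudopopulation
#'
#' Concatenates the cells of several sessions' trial-vector sets, aligning
#' trials by stimulus and within-stimulus trial index (sessions have
#' independent pseudorandom schedules, so this index is the only common
#' alignment key; port labels are taken from the first session).
#'
#' @param vsets list of [TrialVectorSet-class] objects with identical
#'   stimulus sets and trial counts.
#' @return a pooled [TrialVectorSet-class].
#' @export
poolTrialVectors <- function(vsets) {
  .stopIfNot(length(vsets) >= 1, "'vsets' must be a non-empty list")
  ref <- vsets[[1L]]@trialMeta
  for (v in vsets[-1L])
    .stopIfNot(identical(v@trialMeta$stimulus, ref$stimulus) &&
                 identical(v@trialMeta$trial, ref$trial),
               "trial structure differs between sessions; cannot pool")
  vectors <- do.call(cbind, lapply(vsets, methods::slot, "vectors"))
  colnames(vectors) <- make.unique(colnames(vectors))
  methods::new("TrialVectorSet", vectors = vectors, trialMeta = ref,
               windowS = vsets[[1L]]@windowS)
}

#' Trial-by-trial Pearson similarity matrix
#'
#' Pearson correlation between every pair of single-trial population
#' vectors, computed across cells. Zero-variance vectors yield undefined
#' correlations; their rows/columns are set to `NA` and excluded from all
#' downstream summaries.
#'
#' @param vset a [TrialVectorSet-class] with at least two cells.
#' @return a [SimilarityMatrix-class].
#' @export
correlationMatrix <- function(vset) {
  .stopIfNot(methods::is(vset, "TrialVectorSet"),
             "'vset' must be a TrialVectorSet")
  .stopIfNot(ncol(vset@vectors) >= 2, "need >= 2 cells per vector")
  r <- .rowCor(vset@vectors, vset@vectors)
  degenerate <- which(apply(vset@vectors, 1L, stats::sd) == 0)
  if (length(degenerate))
    message(length(degenerate),
            " zero-variance trial vector(s) set to NA: trials ",
            paste(degenerate, collapse = ", "))
  valid <- setdiff(seq_len(nrow(r)), degenerate)
  r[cbind(valid, valid)] <- 1
  methods::new("SimilarityMatrix", values = r, trialMeta = vset@trialMeta,
               ordering = "stimulus")
}

#' Same-condition versus different-condition correlation contrast
#'
#' Averages off-diagonal similarity-matrix entries within same-label trial
#' pairs versus across-label pairs. With `by = "odor"`, labels are stimulus
#' identities. With `by = "port"`, labels are odor-port sides and only
#' within-stimulus pairs are compared (same odor / same port vs same odor /
#' different port), so odor identity cannot masquerade as port information.
#' `restrict` limits the analysis to a stimulus subset (e.g. the three
#' odorants, or `"air"` alone for the control contrast).
#'
#' @param sim a [SimilarityMatrix-class].
#' @param by `"odor"` or `"port"`.
#' @param restrict optional character vector of stimuli to keep.
#' @return list with `same`, `different` (mean correlations), `difference`,
#'   and pair counts `nSame`, `nDifferent`.
#' @export
sameVsDifferent <- function(sim, by = c("odor", "port"), restrict = NULL) {
  by <- match.arg(by)
  .stopIfNot(methods::is(sim, "SimilarityMatrix"),
             "'sim' must be a SimilarityMatrix")
  meta <- sim@trialMeta
  keep <- if (is.null(restrict)) rep(TRUE, nrow(meta))
          else meta$stimulus %in% restrict
  v <- sim@values[keep, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  if (by == "port") {
    .stopIfNot(!is.null(meta$port) && !all(meta$port == "none"),
               "port metadata required for by = 'port'")
    cnt <- table(meta$port[meta$port != "none"])
    if (any(cnt < 2))
      warning("port label(s) with < 2 trials excluded from the contrast")
  }
  n <- nrow(v)
  iu <- which(upper.tri(v), arr.ind = TRUE)  # each unordered pair once
  vals <- v[upper.tri(v)]
  ok <- !is.na(vals)
  i <- iu[ok, 1L]; j <- iu[ok, 2L]; vals <- vals[ok]
  if (by == "odor") {
    same <- meta$stimulus[i] == meta$stimulus[j]
    use <- rep(TRUE, length(vals))
  } else {
    sameStim <- meta$stimulus[i] == meta$stimulus[j]
    use <- sameStim & meta$port[i] != "none" & meta$port[j] != "none"
    same <- meta$port[i] == meta$port[j]
  }
  list(same = mean(vals[use & same]),
       different = mean(vals[use & !same]),
       difference = mean(vals[use & same]) - mean(vals[use & !same]),
       nSame = sum(use & same), nDifferent = sum(use & !same))
}

#' Compare per-session summary values between two groups
#'
#' Two-sided Mann-Whitney rank-sum comparison of per-session (per-mouse)
#' summary statistics, the group test used for all cross-region contrasts.
#' Exact enumeration is used for small samples (see [rankSum()]).
#'
#' @param valuesA,valuesB numeric vectors of per-session values.
#' @param tails `"two"` (default) or `"one"` (alternative: A greater).
#' @return a [TestResult-class].
#' @export
groupCompare <- function(valuesA, valuesB, tails = c("two", "one")) {
  tails <- match.arg(tails)
  rankSum(valuesA, valuesB,
          alternative = if (tails == "two") "two.sided" else "greater")
}
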