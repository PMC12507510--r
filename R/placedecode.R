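#' Assign track positions to spatial bins
#'
#' Divides the track into `nBins` uniform half-open bins
#' `[i*w, (i+1)*w)` of width `w = trackCm / nBins`; the last bin is closed
#' so the far end of the track belongs to bin `nBins - 1`. Bin indices are
#' 0-based throughout the spatial analyses.
#'
#' @param positions a [TrackTrajectory-class] or numeric vector of positions
#'   in cm.
#' @param nBins number of bins (24 over a 100 cm track by default).
#' @param trackCm track length in cm.
#' @return integer vector of 0-based bin indices.
#' @export
binPositions <- function(positions, nBins = 24, trackCm = 100) {
  if (methods::is(positions, "TrackTrajectory")) {
    trackCm <- positions@trackCm
    positions <- positions@positionCm
  }
  bad <- which(positions < 0 | positions > trackCm)
  if (length(bad))
    stop(sprintf("position out of [0, %g] cm at frame %d (%.3f cm)",
                 trackCm, bad[1L], positions[bad[1L]]))
  w <- trackCm / nBins
  pmin(as.integer(floor(positions / w)), nBins - 1L)
}

#' Running-epoch mask
#'
#' Frames usable for spatial analyses: speed strictly above `vMin` (2 cm/s)
#' and outside the `endBinsExcluded` bins at each end of the track, leaving
#' 20 decodable interior bins in the default 24-bin geometry.
#'
#' @param traj a [TrackTrajectory-class].
#' @param vMin speed threshold in cm/s (strict inequality).
#' @param endBinsExcluded bins dropped at each track end.
#' @param nBins number of spatial bins.
#' @return logical vector per frame.
#' @export
runningMask <- function(traj, vMin = 2, endBinsExcluded = 2, nBins = 24) {
  .stopIfNot(methods::is(traj, "TrackTrajectory"),
             "'traj' must be a TrackTrajectory")
  bins <- binPositions(traj, nBins)
  interior <- bins >= endBinsExcluded & bins <= nBins - 1L - endBinsExcluded
  abs(traj@velocityCmS) > vMin & interior
}

#' Population rate map for one direction and traversal parity
#'
#' Mean normalized activity of every cell in every spatial bin, restricted
#' to running-epoch frames of the stated running direction and traversal
#' parity. Parity is the odd/even ordinal of the traversal within that
#' direction (the cross-validation unit on a shuttle task, where global
#' traversal order alternates directions). Bins never visited under that
#' restriction are flagged unusable.
#'
#' @param traces a normalized [CellTraces-class] (see [normalizeTraces()]).
#' @param traj the matching [TrackTrajectory-class].
#' @param direction `"rightward"` or `"leftward"`.
#' @param parity `"odd"`, `"even"` or `"all"` traversals.
#' @param nBins number of spatial bins.
#' @param vMin,endBinsExcluded running-epoch gate (see [runningMask()]).
#' @return a [PopulationRateMap-class].
#' @export
rateMaps <- function(traces, traj, direction = c("rightward", "leftward"),
                     parity = c("all", "odd", "even"), nBins = 24,
                     vMin = 2, endBinsExcluded = 2) {
  direction <- match.arg(direction)
  parity <- match.arg(parity)
  .stopIfNot(methods::is(traces, "CellTraces"),
             "'traces' must be a CellTraces object")
  m <- traceMatrix(traces)
  .stopIfNot(ncol(m) == length(traj@positionCm),
             "traces and trajectory must have the same number of frames")
  sel <- runningMask(traj, vMin, endBinsExcluded, nBins) &
    traj@direction == direction
  if (parity != "all")
    sel <- sel & traj@traversalIndex %in%
      .traversalParity(traj, direction)[[parity]]
  bins <- binPositions(traj, nBins)
  occupancy <- tabulate(bins[sel] + 1L, nbins = nBins)
  rates <- matrix(NA_real_, nrow = nBins, ncol = nrow(m),
                  dimnames = list(NULL, rownames(m)))
  for (b in which(occupancy > 0))
    rates[b, ] <- rowMeans(m[, sel & bins == b - 1L, drop = FALSE])
  interior <- seq_len(nBins) - 1L >= endBinsExcluded &
    seq_len(nBins) - 1L <= nBins - 1L - endBinsExcluded
  methods::new("PopulationRateMap", rates = rates, occupancy = occupancy,
               direction = direction, parity = parity, nBins = nBins,
               trackCm = traj@trackCm, usableBins = interior & occupancy > 0)
}

#' Decode one frame by maximum template correlation
#'
#' The decoded position is the spatial bin whose template population vector
#' has the highest Pearson correlation with the frame's activity vector.
#' Undefined correlations (zero variance) rank below every defined one;
#' ties resolve to the lowest bin index (correlations within 1e-12 of the
#' maximum count as tied, making the tie-break stable under floating-point
#' noise); a frame with no defined correlation at all is undecodable (`NA`).
#'
#' @param frameActivity numeric vector, one entry per cell.
#' @param template a [PopulationRateMap-class].
#' @return 0-based decoded bin index, or `NA_integer_`.
#' @export
decodeFrame <- function(frameActivity, template) {
  .stopIfNot(length(frameActivity) == ncol(template@rates),
             "frame activity and template must cover the same cells")
  usable <- which(template@usableBins)
  r <- vapply(usable, function(b)
    .safeCor(frameActivity, template@rates[b, ]), numeric(1))
  if (all(is.na(r))) return(NA_integer_)
  r[is.na(r)] <- -Inf
  usable[which(r >= max(r) - 1e-12)[1L]] - 1L
}

# Vectorized frame decoding: frames x cells matrix -> 0-based bins.
# Same epsilon tie-break as decodeFrame.
.decodeFrames <- function(frameMatrix, template) {
  usable <- which(template@usableBins)
  r <- .rowCor(frameMatrix, template@rates[usable, , drop = FALSE])
  r[is.na(r)] <- -Inf
  mx <- apply(r, 1L, max)
  out <- usable[max.col(r >= mx - 1e-12, ties.method = "first")] - 1L
  out[!is.finite(mx)] <- NA_integer_
  as.integer(out)
}

#' Decode position across a session
#'
#' Maximum-correlation position decoding with cross-validation.
#' `mode = "same_direction"`: frames on odd traversals are decoded from
#' even-traversal templates of the same running direction, and vice versa.
#' `mode = "cross_direction"`: templates built from one direction decode the
#' other direction's frames (no parity split). With `scoring = "mirrored"`,
#' decoded bins are scored against the mirror-image of the true position
#' (the matched trajectory phase) instead of the allocentric position —
#' the comparison that reveals trajectory-phase codes.
#'
#' @param traces a normalized [CellTraces-class].
#' @param traj the matching [TrackTrajectory-class].
#' @param mode `"same_direction"` or `"cross_direction"`.
#' @param scoring `"allocentric"` or `"mirrored"` (cross-direction only).
#' @param nBins,vMin,endBinsExcluded geometry and running-epoch gate.
#' @param shuffleTemplates if `TRUE`, the spatial identity of each
#'   template's usable bins is randomly permuted before decoding (used by
#'   [positionShuffleNull()]).
#' @return a [PositionDecodingResult-class]; squared errors are in bin^2
#'   (multiply by `binWidthCm^2` for cm^2).
#' @export
decodePosition <- function(traces, traj,
                           mode = c("same_direction", "cross_direction"),
                           scoring = c("allocentric", "mirrored"),
                           nBins = 24, vMin = 2, endBinsExcluded = 2,
                           shuffleTemplates = FALSE) {
  mode <- match.arg(mode)
  scoring <- match.arg(scoring)
  m <- traceMatrix(traces)
  bins <- binPositions(traj, nBins)
  run <- runningMask(traj, vMin, endBinsExcluded, nBins)
  dirs <- c("rightward", "leftward")
  nTrav <- vapply(dirs, function(d)
    length(unique(traj@traversalIndex[run & traj@direction == d])),
    numeric(1))
  if (any(nTrav < 2))
    stop("insufficient traversals for cross-validated decoding (need >= 2 per direction)")
  decoded <- integer(0); truth <- integer(0)
  pairsOf <- function(d, p) {
    sel <- run & traj@direction == d
    if (!is.null(p))
      sel <- sel & traj@traversalIndex %in% .traversalParity(traj, d)[[p]]
    sel
  }
  addBlock <- function(testSel, template) {
    if (!any(testSel)) return()
    if (shuffleTemplates) template <- .permuteTemplate(template)
    dec <- .decodeFrames(t(m[, testSel, drop = FALSE]), template)
    tru <- bins[testSel]
    if (scoring == "mirrored") tru <- nBins - 1L - tru
    ok <- !is.na(dec)
    decoded <<- c(decoded, dec[ok])
    truth <<- c(truth, tru[ok])
  }
  if (mode == "same_direction") {
    for (d in dirs) for (p in c("odd", "even")) {
      template <- rateMaps(traces, traj, d,
                           parity = if (p == "odd") "even" else "odd",
                           nBins = nBins, vMin = vMin,
                           endBinsExcluded = endBinsExcluded)
      addBlock(pairsOf(d, p), template)
    }
  } else {
    for (d in dirs) {
      template <- rateMaps(traces, traj, setdiff(dirs, d), parity = "all",
                           nBins = nBins, vMin = vMin,
                           endBinsExcluded = endBinsExcluded)
      addBlock(pairsOf(d, NULL), template)
    }
  }
  se <- as.numeric((decoded - truth)^2)
  methods::new("PositionDecodingResult", decodedBin = as.integer(decoded),
               trueBin = as.integer(truth), squaredErrors = se, mse = mean(se),
               medianAbsError = stats::median(abs(decoded - truth)),
               mode = mode, scoring = scoring, nBins = nBins,
               binWidthCm = traj@trackCm / nBins)
}

#' Template-shuffle null distribution for position decoding
#'
#' Repeats [decodePosition()] with the spatial identity of the template bins
#' randomly permuted (within each template's usable bins), destroying the
#' position code while preserving every marginal statistic. The resulting
#' distribution of mean squared errors is the chance benchmark for observed
#' decoding performance.
#'
#' @param traces,traj,mode,nBins,vMin,endBinsExcluded as [decodePosition()].
#' @param nShuffles number of shuffles.
#' @param seed RNG seed.
#' @return list with `observed` ([PositionDecodingResult-class]), `nullMse`
#'   (numeric vector) and `pValue`, the fraction of shuffles with mse at or
#'   below the observed (small = better-than-chance decoding).
#' @export
positionShuffleNull <- function(traces, traj, mode = "same_direction",
                                nShuffles = 100, seed = 1, nBins = 24,
                                vMin = 2, endBinsExcluded = 2) {
  observed <- decodePosition(traces, traj, mode = mode, nBins = nBins,
                             vMin = vMin, endBinsExcluded = endBinsExcluded)
  set.seed(as.integer(seed))
  nullMse <- vapply(seq_len(nShuffles), function(i)
    decodePosition(traces, traj, mode = mode, nBins = nBins, vMin = vMin,
                   endBinsExcluded = endBinsExcluded,
                   shuffleTemplates = TRUE)@mse, numeric(1))
  list(observed = observed, nullMse = nullMse,
       pValue = (sum(nullMse <= observed@mse) + 1) / (nShuffles + 1))
}

# Odd/even split of the traversals OF ONE DIRECTION: on a shuttle task the
# two directions strictly alternate, so the global traversal parity is
# confounded with direction; the cross-validation unit is the k-th
# traversal in the given direction.
.traversalParity <- function(traj, direction) {
  ids <- sort(unique(traj@traversalIndex[traj@direction == direction]))
  list(odd = ids[seq_along(ids) %% 2L == 1L],
       even = ids[seq_along(ids) %% 2L == 0L])
}

# Randomly permute the spatial identity of a template's usable bins.
.permuteTemplate <- function(template) {
  usable <- which(template@usableBins)
  perm <- sample(usable)
  template@rates[usable, ] <- template@rates[perm, , drop = FALSE]
  template
}

#' Position-by-direction correlation structure and differentiation index
#'
#' Correlates population activity vectors between every pair of (spatial
#' bin, running direction) combinations and summarizes how strongly the two
#' directions' spatial representations differ. Both operands of the index
#' are split-half correlations: `cSame` correlates odd- and even-traversal
#' maps of the same direction at matched positions; `cDiff` correlates
#' odd-traversal maps of one direction with even-traversal maps of the other
#' at the mirror-symmetric position (matched trajectory phase). The
#' differentiation index `(cSame - cDiff) / (cSame + cDiff)` approaches 1
#' for fully direction-specific codes and 0 for trajectory-phase codes; it
#' is undefined (NA, with a warning) when `cSame + cDiff <= 0`.
#' `phaseReference = "allocentric"` instead matches `cDiff` at the same
#' allocentric position in both directions.
#'
#' @param traces a normalized [CellTraces-class].
#' @param traj the matching [TrackTrajectory-class].
#' @param nBins,vMin,endBinsExcluded geometry and running-epoch gate.
#' @param phaseReference `"mirrored"` (trajectory phase, default) or
#'   `"allocentric"` for the cross-direction matching of `cDiff`.
#' @return a [DirectionCorrelationStructure-class]; the full `corr` matrix
#'   is `(2 * nBins)^2` with rightward bins first, built from all-traversal
#'   maps.
#' @export
directionCorrelation <- function(traces, traj, nBins = 24, vMin = 2,
                                 endBinsExcluded = 2,
                                 phaseReference = c("mirrored",
                                                    "allocentric")) {
  phaseReference <- match.arg(phaseReference)
  maps <- list()
  for (d in c("rightward", "leftward"))
    for (p in c("all", "odd", "even"))
      maps[[paste(d, p)]] <- rateMaps(traces, traj, d, p, nBins = nBins,
                                      vMin = vMin,
                                      endBinsExcluded = endBinsExcluded)
  stacked <- rbind(maps[["rightward all"]]@rates, maps[["leftward all"]]@rates)
  corr <- .rowCor(ifelse(is.na(stacked), 0, stacked),
                  ifelse(is.na(stacked), 0, stacked))
  unusable <- c(!maps[["rightward all"]]@usableBins,
                !maps[["leftward all"]]@usableBins)
  corr[unusable, ] <- NA_real_
  corr[, unusable] <- NA_real_
  rownames(corr) <- colnames(corr) <-
    c(sprintf("R%02d", seq_len(nBins) - 1L),
      sprintf("L%02d", seq_len(nBins) - 1L))

  corAt <- function(mapA, mapB, binA, binB) {
    if (!mapA@usableBins[binA + 1L] || !mapB@usableBins[binB + 1L])
      return(NA_real_)
    .safeCor(mapA@rates[binA + 1L, ], mapB@rates[binB + 1L, ])
  }
  allBins <- seq_len(nBins) - 1L
  cSameVals <- c(
    vapply(allBins, function(b)
      corAt(maps[["rightward odd"]], maps[["rightward even"]], b, b),
      numeric(1)),
    vapply(allBins, function(b)
      corAt(maps[["leftward odd"]], maps[["leftward even"]], b, b),
      numeric(1)))
  mirror <- function(b) if (phaseReference == "mirrored") nBins - 1L - b else b
  cDiffVals <- c(
    vapply(allBins, function(b)
      corAt(maps[["rightward odd"]], maps[["leftward even"]], b, mirror(b)),
      numeric(1)),
    vapply(allBins, function(b)
      corAt(maps[["rightward even"]], maps[["leftward odd"]], b, mirror(b)),
      numeric(1)))
  cSame <- mean(cSameVals, na.rm = TRUE)
  cDiff <- mean(cDiffVals, na.rm = TRUE)
  idx <- if (cSame + cDiff <= 0) {
    warning("differentiation index undefined: cSame + cDiff <= 0")
    NA_real_
  } else (cSame - cDiff) / (cSame + cDiff)
  methods::new("DirectionCorrelationStructure", corr = corr, cSame = cSame,
               cDiff = cDiff, differentiationIndex = idx, nBins = nBins)
}
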