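# CSV schemas
# traces:     frame, <one column per cell> (frames in rows)
# events:     trial, onset_frame, stimulus, port, reward_frame
# trajectory: frame, position_cm, velocity_cm_s, direction, traversal_index

#' Write / read cell traces as CSV
#'
#' Traces are stored frames-in-rows with a leading `frame` column and one
#' column per cell; orientation is normalized back to cells x frames on
#' read. Frame rate and session metadata travel in a JSON sidecar
#' (`<path>.meta.json`).
#'
#' @param traces a [CellTraces-class].
#' @param path CSV file path.
#' @return `writeCellTraces` returns `path` invisibly; `readCellTraces`
#'   returns a [CellTraces-class].
#' @export
writeCellTraces <- function(traces, path) {
  m <- traceMatrix(traces)
  df <- data.frame(frame = seq_len(ncol(m)), t(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  md <- S4Vectors::metadata(traces)
  jsonlite::write_json(md, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCellTraces
#' @param frameRate fallback frame rate if no metadata sidecar is present.
#' @export
readCellTraces <- function(path, frameRate = 20) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"frame" %in% names(df))
    stop("traces schema error: missing column 'frame'")
  m <- t(as.matrix(df[, setdiff(names(df), "frame"), drop = FALSE]))
  md <- list(frame_rate_hz = frameRate, design = "head_fixed",
             region = NA_character_, mouse = NA_character_,
             normalized = FALSE)
  metaPath <- paste0(path, ".meta.json")
  if (file.exists(metaPath)) {
    got <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    md[names(got)] <- got
  }
  cellTraces(m, frameRate = md$frame_rate_hz, cellIds = rownames(m),
             design = md$design,
             region = if (is.null(md$region)) NA_character_ else md$region,
             mouse = if (is.null(md$mouse)) NA_character_ else md$mouse,
             normalized = isTRUE(md$normalized))
}

#' Write / read the behavioural event table
#'
#' @param events data.frame with columns `trial`, `onset_frame`,
#'   `stimulus`, `port`, `reward_frame`.
#' @param path CSV file path.
#' @export
writeEventTable <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  events <- utils::read.csv(path)
  .checkEventTable(events)
  events
}

#' Write / read a track trajectory
#'
#' @param traj a [TrackTrajectory-class].
#' @param path CSV file path.
#' @export
writeTrackTrajectory <- function(traj, path) {
  df <- data.frame(frame = seq_along(traj@positionCm),
                   position_cm = traj@positionCm,
                   velocity_cm_s = traj@velocityCmS,
                   direction = as.character(traj@direction),
                   traversal_index = traj@traversalIndex)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(frame_rate_hz = traj@frameRate,
                            track_cm = traj@trackCm),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTrackTrajectory
#' @param frameRate,trackCm fallbacks if no metadata sidecar is present.
#' @export
readTrackTrajectory <- function(path, frameRate = 20, trackCm = 100) {
  df <- utils::read.csv(path)
  need <- c("position_cm", "velocity_cm_s", "direction", "traversal_index")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory schema error: missing column(s) ",
         paste(sprintf("'%s'", miss), collapse = ", "))
  metaPath <- paste0(path, ".meta.json")
  if (file.exists(metaPath)) {
    got <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    if (!is.null(got$frame_rate_hz)) frameRate <- got$frame_rate_hz
    if (!is.null(got$track_cm)) trackCm <- got$track_cm
  }
  bad <- which(df$position_cm < 0 | df$position_cm > trackCm)
  if (length(bad))
    stop(sprintf("trajectory range error: position %.3f cm at frame %d outside [0, %g]",
                 df$position_cm[bad[1L]], bad[1L], trackCm))
  trackTrajectory(df$position_cm, df$velocity_cm_s, df$direction,
                  df$traversal_index, frameRate = frameRate,
                  trackCm = trackCm)
}

#' Write the ground-truth sidecar of a synthetic session
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON file path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(
    list(odor_tuned = truth@odorTuned, port_tuned = truth@portTuned,
         place_cells = truth@placeCells,
         seed = as.integer(truth@config@seed)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, single-cell metrics, population similarity and
#' odor decoding on one session — plus the spatial analyses when a
#' trajectory is supplied — and returns everything as a result bundle with
#' a provenance record (parameters, seed, package version). When
#' `outputDir` is given, result tables are also written as CSV/JSON.
#'
#' @param traces a [CellTraces-class] (raw).
#' @param events event table data.frame.
#' @param trajectory optional [TrackTrajectory-class] for track sessions.
#' @param design trial-window design; defaults to the traces' metadata.
#' @param smoothWindow smoothing window, frames.
#' @param decodeWindowS sliding decoding window, s.
#' @param decodeTimeRange window-start range for decoding, s; `NULL` decodes
#'   the full trial.
#' @param nBins,vMin,endBinsExcluded spatial-analysis parameters.
#' @param seed seed recorded in provenance and used for stochastic stages.
#' @param outputDir optional directory for result files.
#' @return a named list: `tensor`, `activation`, `pctResponsive`,
#'   `magnitude`, `durations`, `similarity`, `contrastOdor`, `decoding`,
#'   and for track sessions `contrastPort`, `positionDecoding`,
#'   `directionCorrelation`; plus `provenance`.
#' @export
runPipeline <- function(traces, events, trajectory = NULL, design = NULL,
                        smoothWindow = 5, decodeWindowS = 0.25,
                        decodeTimeRange = NULL, nBins = 24, vMin = 2,
                        endBinsExcluded = 2, seed = 1, outputDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(design)) design <- S4Vectors::metadata(traces)$design
  tensor <- stage("preprocess",
                  buildTensor(traces, events, design, smoothWindow))
  mask <- stage("cellmetrics", detectActivated(tensor))
  pct <- pctResponsive(mask, per = "stimulus")
  mag <- responseMagnitude(tensor, mask)
  dur <- responseDuration(tensor)
  vset <- stage("similarity", trialVectors(tensor))
  sim <- correlationMatrix(vset)
  odorStim <- setdiff(tensor@stimuli, "air")
  contrastOdor <- sameVsDifferent(sim, by = "odor", restrict = odorStim)
  set.seed(as.integer(seed))
  decoding <- stage("odordecode",
                    decodeOdors(tensor, windowS = decodeWindowS,
                                timeRange = decodeTimeRange))
  out <- list(tensor = tensor, activation = mask, pctResponsive = pct,
              magnitude = mag, durations = dur, similarity = sim,
              contrastOdor = contrastOdor, decoding = decoding)
  if (!is.null(trajectory)) {
    normTr <- stage("placedecode", normalizeTraces(traces, smoothWindow))
    out$contrastPort <- sameVsDifferent(sim, by = "port",
                                        restrict = odorStim)
    out$positionDecoding <- stage("placedecode",
      decodePosition(normTr, trajectory, mode = "same_direction",
                     nBins = nBins, vMin = vMin,
                     endBinsExcluded = endBinsExcluded))
    out$directionCorrelation <- stage("placedecode",
      directionCorrelation(normTr, trajectory, nBins = nBins, vMin = vMin,
                           endBinsExcluded = endBinsExcluded))
  }
  out$provenance <- list(
    package = "odorplace",
    version = as.character(utils::packageVersion("odorplace")),
    design = design, seed = seed,
    parameters = list(smoothWindow = smoothWindow,
                      decodeWindowS = decodeWindowS,
                      decodeTimeRange = decodeTimeRange, nBins = nBins,
                      vMin = vMin, endBinsExcluded = endBinsExcluded),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(outputDir)) .writeBundle(out, outputDir)
  out
}

.writeBundle <- function(bundle, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outputDir, f)
  utils::write.csv(data.frame(stimulus = names(bundle$pctResponsive),
                              pct_responsive = bundle$pctResponsive),
                   fp("pct_responsive.csv"), row.names = FALSE)
  utils::write.csv(bundle$magnitude$values, fp("response_magnitude.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$durations, fp("response_duration.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$similarity@values, fp("similarity_matrix.csv"),
                   row.names = FALSE)
  dec <- bundle$decoding
  utils::write.csv(data.frame(time_s = dec@timePoints,
                              accuracy = dec@accuracySeries,
                              p_value = dec@pSeries),
                   fp("decoding_timecourse.csv"), row.names = FALSE)
  summaryList <- list(
    pct_responsive = as.list(bundle$pctResponsive),
    magnitude_mean = bundle$magnitude$mean,
    odor_contrast = bundle$contrastOdor,
    decoding_overall_accuracy = dec@overallAccuracy,
    provenance = bundle$provenance)
  if (!is.null(bundle$positionDecoding)) {
    pd <- bundle$positionDecoding
    summaryList$position_mse_bins2 <- pd@mse
    summaryList$position_median_abs_error_bins <- pd@medianAbsError
    summaryList$differentiation_index <-
      bundle$directionCorrelation@differentiationIndex
    summaryList$port_contrast <- bundle$contrastPort
  }
  jsonlite::write_json(summaryList, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outputDir)
}
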