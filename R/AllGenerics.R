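#' Accessor generics
#'
#' Small accessor family used across the package's S4 classes.
#'
#' @param x an odorplace object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("traceMatrix", function(x) standardGeneric("traceMatrix"))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))

#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname accessors
#' @export
setGeneric("trialMeta", function(x) standardGeneric("trialMeta"))

#' @rdname accessors
#' @export
setGeneric("stimuli", function(x) standardGeneric("stimuli"))

#' @rdname accessors
#' @export
setGeneric("accuracySeries", function(x) standardGeneric("accuracySeries"))

#' @rdname accessors
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname accessors
#' @export
setGeneric("pSeries", function(x) standardGeneric("pSeries"))

#' @rdname accessors
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))

#' @rdname accessors
#' @export
setGeneric("differentiationIndex", function(x) standardGeneric("differentiationIndex"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
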