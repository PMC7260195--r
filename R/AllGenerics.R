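#' Accessor generics
#'
#' Standard accessors for the package's S4 classes.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname accessors
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))

#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname accessors
#' @export
setGeneric("transformState", function(x) standardGeneric("transformState"))

#' @rdname accessors
#' @export
setGeneric("droppedRows", function(x) standardGeneric("droppedRows"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("gateNodes", function(x) standardGeneric("gateNodes"))

#' @rdname accessors
#' @export
setGeneric("membership", function(x, alias) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("countsTable", function(x, ...) standardGeneric("countsTable"))

#' @rdname accessors
#' @export
setGeneric("isFlagged", function(x) standardGeneric("isFlagged"))

#' @rdname accessors
#' @export
setGeneric("subsetCounts", function(x) standardGeneric("subsetCounts"))

#' @rdname accessors
#' @export
setGeneric("annotationRecords", function(x) standardGeneric("annotationRecords"))

#' @rdname accessors
#' @export
setGeneric("effectiveTags", function(x) standardGeneric("effectiveTags"))
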