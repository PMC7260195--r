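#' @import methods
NULL

#' EventMatrix: a per-sample table of cytometry events
#'
#' The substrate of all gating: an events x channels numeric matrix together
#' with the per-channel transform state and free-form acquisition metadata.
#' Rows containing NaN are dropped at construction and counted in
#' `droppedRows(x)`; gating counts are defined over retained events.
#'
#' @slot sampleId single sample identifier.
#' @slot data numeric matrix, events in rows, channels in columns; column
#'   names are the channel names.
#' @slot transformState named character vector, one entry per channel, e.g.
#'   `"linear"` or `"arcsinh(cofactor=150)"`.
#' @slot metadata named list of free-form strings (instrument, date,
#'   technician id, ...).
#' @slot droppedRows number of input rows removed because they contained
#'   NaN/non-numeric values.
#'
#' @seealso [EventMatrix()], [readFCS()], [readEventsCSV()], [applyTransform()]
#' @export
setClass("EventMatrix",
  representation(sampleId = "character", data = "matrix",
                 transformState = "character", metadata = "list",
                 droppedRows = "integer"))

setValidity("EventMatrix", function(object) {
  d <- object@data
  msgs <- character()
  if (nrow(d) < 1) msgs <- c(msgs, "EventMatrix must contain at least one event")
  cn <- colnames(d)
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
    msgs <- c(msgs, "channel names must be present and unique")
  if (anyNA(d)) msgs <- c(msgs, "event data must not contain NA/NaN after load")
  ts <- object@transformState
  if (!is.null(cn) && (!all(cn %in% names(ts)) || length(ts) != length(cn)))
    msgs <- c(msgs, "transformState must cover every channel exactly once")
  if (length(object@sampleId) != 1) msgs <- c(msgs, "sampleId must be length 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EventMatrix
#'
#' Rows with any non-finite (NA/NaN) value are dropped and counted; the count
#' is added to any `droppedRows` passed in (e.g. rows already removed by a
#' reader).
#'
#' @param data numeric matrix or data.frame with channel names as column names.
#' @param sampleId sample identifier.
#' @param transformState optional named character vector channel -> transform
#'   label; defaults to `"linear"` for every channel.
#' @param metadata named list of strings.
#' @param droppedRows rows already dropped upstream.
#' @return An [EventMatrix-class] object.
#' @examples
#' em <- EventMatrix(matrix(rnorm(20), 10, 2,
#'                          dimnames = list(NULL, c("FSC-A", "CD3"))),
#'                   sampleId = "s1")
#' nEvents(em)
#' @export
EventMatrix <- function(data, sampleId = "sample", transformState = NULL,
                        metadata = list(), droppedRows = 0L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  keep <- stats::complete.cases(data) & apply(is.finite(data), 1, all)
  dropped <- as.integer(droppedRows) + sum(!keep)
  data <- data[keep, , drop = FALSE]
  if (is.null(transformState)) {
    transformState <- stats::setNames(rep("linear", ncol(data)), colnames(data))
  }
  new("EventMatrix", sampleId = as.character(sampleId), data = data,
      transformState = transformState[colnames(data)], metadata = metadata,
      droppedRows = dropped)
}

#' GatingTemplate: a parsed hierarchical gating template
#'
#' An ordered set of template rows (alias, parent, dims, method, sign, args)
#' in topological order; the text representation is a CSV, one row per gate
#' (see [parseGatingTemplate()]).
#'
#' @slot rows list of template rows; each row is a list with elements
#'   `alias`, `parent`, `dims` (character vector of 1-2 channels), `method`,
#'   `sign`, `args` (named list of typed arguments).
#' @export
setClass("GatingTemplate", representation(rows = "list"))

TEMPLATE_METHODS <- c("mindensity", "quadrant", "rect", "singlet",
                      "boolean", "kmeans_subsets")

setValidity("GatingTemplate", function(object) {
  rows <- object@rows
  if (!length(rows)) return("template must contain at least one row")
  aliases <- vapply(rows, `[[`, "", "alias")
  if (anyDuplicated(aliases)) return("duplicate alias in template")
  seen <- "root"
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (!r$method %in% TEMPLATE_METHODS)
      return(sprintf("unknown method '%s' at row %d", r$method, i))
    if (!r$parent %in% seen)
      return(sprintf("orphan parent '%s' at row %d", r$parent, i))
    seen <- c(seen, r$alias)
  }
  TRUE
})

#' GateNode: fitted gate geometry for one template row on one sample
#'
#' @slot alias population alias.
#' @slot parent parent alias ("root" for the top level).
#' @slot kind gating method that produced the geometry.
#' @slot dims channel name(s) the gate was fitted on.
#' @slot geometry named list: 1D cut point `cut`; rectangle
#'   `x1,x2,y1,y2`; quadrant `cx,cy,quadrant`; singlet
#'   `slope,band`; empty when the gate errored.
#' @slot error character; the gate failure message, or `NA` on success.
#' @export
setClass("GateNode",
  representation(alias = "character", parent = "character", kind = "character",
                 dims = "character", geometry = "list", error = "character"))

#' PopulationResult: per-population membership and counts
#'
#' @slot alias population alias.
#' @slot parent parent alias.
#' @slot membership logical event mask over the sample's events.
#' @slot count number of member events (`NA` when the gate errored).
#' @slot pctOfParent percent of the parent population (0 with a
#'   "low_cell_count" flag when the parent is empty).
#' @slot pctOfTotal percent of all retained events.
#' @slot absCount absolute count in 10^9 cells/L (`NA` without a WBC count).
#' @slot flags character vector of annotation-vocabulary flags attached
#'   during gating (e.g. "low_cell_count", "needs_manual_refinement").
#' @export
setClass("PopulationResult",
  representation(alias = "character", parent = "character",
                 membership = "logical", count = "integer",
                 pctOfParent = "numeric", pctOfTotal = "numeric",
                 absCount = "numeric", flags = "character"))

#' GatingResult: all populations and fitted gates for one sample
#'
#' Returned by [applyTemplate()]; query with [populations()], [gateNodes()],
#' [membership()] and [countsTable()].
#'
#' @slot sampleId sample identifier.
#' @slot nEvents number of retained events in the sample (the root count).
#' @slot populations named list of [PopulationResult-class], in template order.
#' @slot nodes named list of [GateNode-class], in template order.
#' @export
setClass("GatingResult",
  representation(sampleId = "character", nEvents = "integer",
                 populations = "list", nodes = "list"))

#' SubsetCall: output of the three-marker k-means T-cell subset caller
#'
#' @slot assignment integer cluster id (1..4) per event.
#' @slot clusterSigns 4 x 3 character matrix of "+"/"-" per cluster for
#'   (CCR7, CD45RA, CD28).
#' @slot subsetLabels character(4): subset name per cluster.
#' @slot flagged TRUE when the sample is routed to manual gating (the four
#'   CCR7/CD45RA sign pairs did not map one-to-one onto the subsets).
#' @slot counts data.frame with columns parent, subset, count, pct_of_parent:
#'   the eight output populations.
#' @slot seed integer seed the clustering was run under.
#' @slot notes character vector of warnings (e.g. CD28 consistency mismatches).
#' @export
setClass("SubsetCall",
  representation(assignment = "integer", clusterSigns = "matrix",
                 subsetLabels = "character", flagged = "logical",
                 counts = "data.frame", seed = "integer", notes = "character"))

setValidity("SubsetCall", function(object) {
  s <- object@clusterSigns
  if (!all(dim(s) == c(4, 3))) return("clusterSigns must be 4 x 3")
  if (!all(colSums(s == "+") == 2))
    return("each marker must have exactly two '+' and two '-' clusters")
  TRUE
})

#' AnnotationStore: an append-only store of gate quality annotations
#'
#' Mirrors a keystroke-review workflow: each record tags one (sample, gate)
#' image with a quality label; re-annotation appends and the latest record
#' wins. Persisted as a plain CSV (see [writeAnnotations()]).
#'
#' @slot records data.frame with columns sample_id, gate_alias, tag, analyst,
#'   timestamp (ISO-8601), in append order.
#' @export
setClass("AnnotationStore", representation(records = "data.frame"))

ANNOTATION_TAGS <- c("good", "bad", "needs_manual_refinement", "low_cell_count")
MANUAL_TAGS <- c("bad", "needs_manual_refinement")
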