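#' @describeIn accessors sample identifier of an EventMatrix.
#' @export
setMethod("sampleId", "EventMatrix", function(x) x@sampleId)

#' @describeIn accessors channel names, in acquisition order.
#' @export
setMethod("channels", "EventMatrix", function(x) colnames(x@data))

#' @describeIn accessors the events x channels numeric matrix.
#' @export
setMethod("eventData", "EventMatrix", function(x) x@data)

#' @describeIn accessors number of retained events.
#' @export
setMethod("nEvents", "EventMatrix", function(x) nrow(x@data))

#' @describeIn accessors named per-channel transform labels.
#' @export
setMethod("transformState", "EventMatrix", function(x) x@transformState)

#' @describeIn accessors rows dropped at load for NaN/non-numeric values.
#' @export
setMethod("droppedRows", "EventMatrix", function(x) x@droppedRows)

setMethod("show", "EventMatrix", function(object) {
  cat("EventMatrix '", object@sampleId, "': ", nrow(object@data), " events x ",
      ncol(object@data), " channels\n", sep = "")
  cat("  channels:", paste(utils::head(colnames(object@data), 8), collapse = ", "),
      if (ncol(object@data) > 8) "..." else "", "\n")
  nonlin <- sum(object@transformState != "linear")
  cat("  transforms: ", nonlin, " non-linear channel(s); dropped rows: ",
      object@droppedRows, "\n", sep = "")
})

#' Subset an EventMatrix by events
#'
#' @param x an EventMatrix.
#' @param i logical or integer event index.
#' @param j ignored (channels are selected via [eventData()]).
#' @param ... ignored.
#' @param drop ignored.
#' @return An EventMatrix restricted to the selected events.
#' @export
setMethod("[", "EventMatrix", function(x, i, j, ..., drop = FALSE) {
  initialize(x, data = x@data[i, , drop = FALSE])
})

setMethod("show", "GatingResult", function(object) {
  ok <- vapply(object@populations, function(p) !is.na(p@count), TRUE)
  cat("GatingResult '", object@sampleId, "': ", object@nEvents, " events, ",
      length(object@populations), " populations (", sum(!ok), " errored)\n",
      sep = "")
  for (p in object@populations) {
    cat(sprintf("  %-24s parent=%-12s count=%s pct_of_parent=%s%s\n",
                p@alias, p@parent,
                ifelse(is.na(p@count), "NA", format(p@count)),
                ifelse(is.na(p@pctOfParent), "NA",
                       formatC(p@pctOfParent, digits = 2, format = "f")),
                if (length(p@flags)) paste0(" [", paste(p@flags, collapse = ","), "]")
                else ""))
  }
})

#' @describeIn accessors sample identifier of a GatingResult.
#' @export
setMethod("sampleId", "GatingResult", function(x) x@sampleId)

#' @describeIn accessors retained event count a GatingResult was computed on.
#' @export
setMethod("nEvents", "GatingResult", function(x) x@nEvents)

#' @describeIn accessors named list of PopulationResult objects.
#' @export
setMethod("populations", "GatingResult", function(x) x@populations)

#' @describeIn accessors named list of fitted GateNode objects.
#' @export
setMethod("gateNodes", "GatingResult", function(x) x@nodes)

#' @describeIn accessors logical event mask of one population.
#' @export
setMethod("membership", "GatingResult", function(x, alias) {
  p <- x@populations[[alias]]
  if (is.null(p)) stop("unknown population alias: ", alias)
  p@membership
})

#' @describeIn accessors per-population counts as a data.frame with columns
#'   sample_id, alias, count, pct_of_parent, pct_of_total, abs_count, flags.
#' @export
setMethod("countsTable", "GatingResult", function(x, ...) {
  do.call(rbind, lapply(x@populations, function(p) {
    data.frame(sample_id = x@sampleId, alias = p@alias,
               count = p@count, pct_of_parent = p@pctOfParent,
               pct_of_total = p@pctOfTotal, abs_count = p@absCount,
               flags = paste(p@flags, collapse = "|"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
})

setMethod("show", "SubsetCall", function(object) {
  cat("SubsetCall: ", length(object@assignment), " events, flagged=",
      object@flagged, "\n", sep = "")
  print(object@counts, row.names = FALSE)
})

#' @describeIn accessors TRUE when a SubsetCall is routed to manual gating.
#' @export
setMethod("isFlagged", "SubsetCall", function(x) x@flagged)

#' @describeIn accessors the eight per-parent subset populations of a
#'   SubsetCall (data.frame parent, subset, count, pct_of_parent).
#' @export
setMethod("subsetCounts", "SubsetCall", function(x) x@counts)
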