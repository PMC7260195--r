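# Batch review workflow: pre-generated per-gate images plus a plain-CSV
# annotation store with latest-wins semantics. The interactive keystroke
# GUI of the original review tool is replaced by files any tool can edit;
# the data model (quality tags per sample x gate) and the routing logic to
# manual refinement are preserved.

#' Create an empty annotation store
#'
#' @return An [AnnotationStore-class] with no records.
#' @export
annotationStore <- function() {
  new("AnnotationStore", records = data.frame(
    sample_id = character(), gate_alias = character(), tag = character(),
    analyst = character(), timestamp = character(), stringsAsFactors = FALSE))
}

#' Record a quality annotation
#'
#' Appends one record; re-annotating the same (sample, gate) pair keeps the
#' history and the latest record wins in the effective view.
#'
#' @param store an [AnnotationStore-class].
#' @param sampleId,gateAlias the annotated (sample, gate) pair.
#' @param tag one of `"good"`, `"bad"`, `"needs_manual_refinement"`,
#'   `"low_cell_count"`.
#' @param analyst analyst identifier.
#' @param timestamp ISO-8601 timestamp; defaults to now.
#' @return The updated store.
#' @export
recordAnnotation <- function(store, sampleId, gateAlias, tag,
                             analyst = "analyst",
                             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  if (!tag %in% ANNOTATION_TAGS)
    preconditionError(sprintf("unknown tag '%s'; allowed: %s", tag,
                              paste(ANNOTATION_TAGS, collapse = ", ")))
  rec <- data.frame(sample_id = as.character(sampleId),
                    gate_alias = as.character(gateAlias),
                    tag = tag, analyst = analyst, timestamp = timestamp,
                    stringsAsFactors = FALSE)
  initialize(store, records = rbind(store@records, rec))
}

#' @describeIn accessors the full append-order record history of an
#'   AnnotationStore.
#' @export
setMethod("annotationRecords", "AnnotationStore", function(x) x@records)

#' @describeIn accessors latest-wins effective view of an AnnotationStore:
#'   one row per annotated (sample_id, gate_alias) pair.
#' @export
setMethod("effectiveTags", "AnnotationStore", function(x) {
  r <- x@records
  if (nrow(r) == 0) return(r)
  key <- paste(r$sample_id, r$gate_alias, sep = "\r")
  r[!duplicated(key, fromLast = TRUE), , drop = FALSE]
})

setMethod("show", "AnnotationStore", function(object) {
  eff <- effectiveTags(object)
  cat("AnnotationStore:", nrow(object@records), "records,",
      nrow(eff), "annotated (sample, gate) pairs\n")
  if (nrow(eff)) print(table(eff$tag))
})

#' Persist / reload an annotation store
#'
#' The CSV keeps the full append-order history, so a reload reproduces the
#' latest-wins view exactly.
#'
#' @param store an [AnnotationStore-class].
#' @param path CSV path (columns sample_id,gate_alias,tag,analyst,timestamp).
#' @return `writeAnnotations`: `path` invisibly; `readAnnotations`: the
#'   reloaded store.
#' @export
writeAnnotations <- function(store, path) {
  utils::write.csv(store@records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  bad <- setdiff(df$tag, ANNOTATION_TAGS)
  if (length(bad))
    preconditionError(paste("annotation file contains unknown tag(s):",
                            paste(bad, collapse = ", ")))
  new("AnnotationStore", records = df)
}

#' Summarise annotations and compute the manual hand-off list
#'
#' A (sample, gate) pair is routed to manual refinement when its effective
#' tag is `"bad"` or `"needs_manual_refinement"`. Per gate alias the
#' fraction of batch samples so tagged is reported; the global fraction is
#' the share of batch samples with at least one such tag.
#'
#' @param store an [AnnotationStore-class].
#' @param samples the sample ids of the batch (defaults to the annotated
#'   samples); the denominators of all fractions.
#' @param aliases gate aliases to report (defaults to the annotated ones);
#'   aliases with no annotations get fraction 0 and `reviewed = FALSE`.
#' @return List with `perGate` (data.frame gate_alias, n_flagged, fraction,
#'   reviewed), `globalFraction`, and `flagged` (data.frame sample_id,
#'   gate_alias, tag: the hand-off list for manual re-gating).
#' @export
summarizeTags <- function(store, samples = NULL, aliases = NULL) {
  eff <- effectiveTags(store)
  samples <- as.character(samples %||% unique(eff$sample_id))
  aliases <- as.character(aliases %||% unique(eff$gate_alias))
  eff <- eff[eff$sample_id %in% samples, , drop = FALSE]
  flagged <- eff[eff$tag %in% MANUAL_TAGS,
                 c("sample_id", "gate_alias", "tag"), drop = FALSE]
  perGate <- do.call(rbind, lapply(aliases, function(a) {
    nfl <- sum(flagged$gate_alias == a)
    data.frame(gate_alias = a, n_flagged = nfl,
               fraction = if (length(samples)) nfl / length(samples) else 0,
               reviewed = a %in% eff$gate_alias,
               stringsAsFactors = FALSE)
  }))
  globalFraction <- if (length(samples))
    length(unique(flagged$sample_id)) / length(samples) else 0
  rownames(flagged) <- NULL
  list(perGate = perGate, globalFraction = globalFraction, flagged = flagged)
}

#' Write the manual hand-off list
#'
#' @param summary result of [summarizeTags()].
#' @param path output CSV (columns sample_id,gate_alias,tag).
#' @return `path`, invisibly.
#' @export
writeFlaggedSamples <- function(summary, path) {
  utils::write.csv(summary$flagged, path, row.names = FALSE)
  invisible(path)
}
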