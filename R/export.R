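#' Export fitted gates as JSON
#'
#' Serialises a [GatingResult-class] as
#' `{sample_id, gates: [{alias, parent, kind, dims, geometry, count,
#' pct_of_parent, pct_of_total, error}]}`. Errored gates carry their error
#' message and a null geometry. This is the package's text gate-exchange
#' format (in place of workspace XML round-tripping).
#'
#' @param result a [GatingResult-class].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @seealso [loadGatesJSON()]
#' @export
exportGatesJSON <- function(result, path) {
  gates <- lapply(names(result@populations), function(alias) {
    p <- result@populations[[alias]]
    nd <- result@nodes[[alias]]
    list(alias = alias, parent = p@parent,
         kind = if (is.null(nd)) NA else nd@kind,
         dims = if (is.null(nd)) character() else as.list(nd@dims),
         geometry = if (is.null(nd) || !is.na(nd@error)) NULL else nd@geometry,
         count = p@count, pct_of_parent = p@pctOfParent,
         pct_of_total = p@pctOfTotal, abs_count = p@absCount,
         flags = as.list(p@flags),
         error = if (is.null(nd) || is.na(nd@error)) NULL else nd@error)
  })
  jsonlite::write_json(
    list(sample_id = result@sampleId, n_events = result@nEvents,
         tool_version = toolVersion(), gates = gates),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a gate-export JSON document
#'
#' @param path path written by [exportGatesJSON()].
#' @return A list with `sample_id`, `n_events` and `gates` (a list of gate
#'   records; `geometry` is a named list or `NULL` for errored gates).
#' @export
loadGatesJSON <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Write a per-sample, per-population counts CSV
#'
#' One row per sample x population with header
#' `sample_id,alias,count,pct_of_parent,pct_of_total,abs_count,flags`,
#' preceded by a `#` metadata block (tool version, seed, config hash).
#'
#' @param results a [GatingResult-class] or list of them.
#' @param path output path.
#' @param seed seed recorded in the metadata block.
#' @return `path`, invisibly.
#' @export
writeCountsCSV <- function(results, path, seed = NA) {
  if (is(results, "GatingResult")) results <- list(results)
  tab <- do.call(rbind, lapply(results, countsTable))
  writeTableWithHeader(tab, path, seed = seed,
                       config = lapply(results, sampleId))
}
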