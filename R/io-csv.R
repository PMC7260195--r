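#' Read an event table from CSV
#'
#' Plain-text alternative to FCS input: a comma-separated file whose header
#' row gives the channel names and whose body is numeric. Rows with any
#' non-numeric entry are dropped and counted in `droppedRows()`.
#'
#' @param path path to the CSV file.
#' @param sampleId sample identifier; defaults to the file name.
#' @return An [EventMatrix-class].
#' @export
readEventsCSV <- function(path, sampleId = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "#")
  if (nrow(df) == 0) formatError("event CSV has a header but no data rows")
  num <- as.data.frame(lapply(df, function(col) suppressWarnings(as.numeric(col))),
                       check.names = FALSE)
  keep <- stats::complete.cases(num)
  if (!any(keep)) formatError("event CSV contains no fully numeric rows")
  nd <- sum(!keep)
  if (nd > 0) message(sprintf("readEventsCSV: dropped %d non-numeric row(s)", nd))
  EventMatrix(as.matrix(num[keep, , drop = FALSE]),
              sampleId = sampleId %||% sub("\\.csv$", "", basename(path)),
              droppedRows = nd)
}

#' Write an EventMatrix as a plain events CSV
#'
#' @param x an [EventMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEventsCSV <- function(x, path) {
  utils::write.csv(as.data.frame(eventData(x), check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a white-blood-cell count table
#'
#' Two-column CSV `sample_id,wbc` with counts in 10^9 cells/L; used to turn
#' percent-of-total into absolute counts (absolute count = fraction of total
#' events x WBC).
#'
#' @param path path to the CSV file.
#' @return Named numeric vector, sample_id -> WBC.
#' @export
readWbcTable <- function(path) {
  df <- readTableSkipHeader(path)
  if (!all(c("sample_id", "wbc") %in% names(df)))
    formatError("WBC table must have columns sample_id,wbc")
  wbc <- as.numeric(df$wbc)
  if (anyNA(wbc) || any(wbc <= 0))
    formatError("WBC counts must be positive numbers")
  stats::setNames(wbc, as.character(df$sample_id))
}
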