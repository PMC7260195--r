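# Internal condition constructors. All package errors inherit "cytoError" so
# callers can trap pipeline failures without matching on message text; the
# subclass records which contract was violated.

cytoStop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "cytoError", "error")))
}

formatError <- function(msg, keyword = NULL) {
  if (!is.null(keyword)) msg <- sprintf("%s (keyword %s)", msg, keyword)
  cytoStop(msg, "cytoFormatError", keyword = keyword)
}

templateError <- function(msg, row = NA_integer_) {
  if (!is.na(row)) msg <- sprintf("%s at row %d", msg, row)
  cytoStop(msg, "cytoTemplateError", row = row)
}

# Gate failures carry an annotation-vocabulary tag ("needs_manual_refinement",
# "low_cell_count") so applyTemplate can route the subtree instead of aborting.
gateError <- function(msg, tag = "needs_manual_refinement") {
  cytoStop(msg, "cytoGateError", tag = tag)
}

preconditionError <- function(msg) {
  cytoStop(msg, "cytoPreconditionError")
}

gateErrorTag <- function(e) {
  tag <- conditionCall(e)
  t <- e$tag
  if (is.null(t)) "needs_manual_refinement" else t
}

#' @importFrom utils packageVersion
toolVersion <- function() as.character(utils::packageVersion("cytoHybrid"))

# Polynomial rolling hash (mod 2^31 - 1) of a deparsed object; used to
# stamp output files with a configuration fingerprint without adding a
# digest dependency.
configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

runHeader <- function(seed = NA, config = list()) {
  c(sprintf("# cytoHybrid %s", toolVersion()),
    sprintf("# seed=%s config=%s", as.character(seed), configHash(config)))
}

# Write a data.frame as CSV preceded by the '#' metadata header block.
writeTableWithHeader <- function(df, path, seed = NA, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(runHeader(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

readTableSkipHeader <- function(path, ...) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
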