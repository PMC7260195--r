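# Template CSV dialect
#
# Columns: alias,parent,dims,method,sign,args
#   dims : 1 or 2 channel names joined by ':'           e.g. "CD3:CD19"
#   sign : one '+'/'-' per dim                          e.g. "+-"
#   args : semicolon-separated key=value pairs; values in [..] parse to
#          numeric vectors, bare numbers to numerics, 'a:b:c' lists of
#          names stay character vectors.
#          e.g. "gate_range=[0,5];min_peak_height=0.05;expected_peaks=2"

parseArgValue <- function(v) {
  v <- trimws(v)
  if (grepl("^\\[.*\\]$", v)) {
    return(as.numeric(strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]]))
  }
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  if (grepl(":", v, fixed = TRUE)) return(strsplit(v, ":", fixed = TRUE)[[1]])
  v
}

parseArgs <- function(s) {
  s <- trimws(s %||% "")
  if (!nzchar(s)) return(list())
  pairs <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in pairs) {
    p <- trimws(p)
    if (!nzchar(p)) next
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) templateError(sprintf("malformed args entry '%s'", p))
    out[[trimws(substr(p, 1, eq - 1))]] <- parseArgValue(substr(p, eq + 1, nchar(p)))
  }
  out
}

#' Parse a hierarchical gating template from CSV
#'
#' Reads the text template that drives [applyTemplate()]: one row per gate
#' with columns `alias,parent,dims,method,sign,args`. Rows must be in
#' topological order (every parent declared earlier or `"root"`). Supported
#' methods: `mindensity` (1D density-valley cut), `quadrant`, `rect`,
#' `singlet` (FSC-A/FSC-H doublet exclusion), `boolean` (expression over
#' earlier aliases) and `kmeans_subsets` (delegates to [callSubsets()]).
#'
#' @param path path to the template CSV.
#' @return A validated [GatingTemplate-class].
#' @seealso [applyTemplate()]; an example template ships in
#'   `system.file("extdata", "hip_template_synthetic.csv", package = "cytoHybrid")`.
#' @export
parseGatingTemplate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        comment.char = "#", colClasses = "character")
  needed <- c("alias", "parent", "dims", "method")
  if (!all(needed %in% names(df)))
    templateError(paste("template CSV must have columns",
                        paste(needed, collapse = ",")))
  if (nrow(df) == 0) templateError("template has no rows")
  rows <- vector("list", nrow(df))
  seen <- "root"
  for (i in seq_len(nrow(df))) {
    alias <- trimws(df$alias[i])
    parent <- trimws(df$parent[i])
    method <- trimws(df$method[i])
    dims <- trimws(strsplit(df$dims[i], ":", fixed = TRUE)[[1]])
    dims <- dims[nzchar(dims)]
    sign <- trimws(if ("sign" %in% names(df)) df$sign[i] else "")
    args <- parseArgs(if ("args" %in% names(df)) df$args[i] else "")
    if (!nzchar(alias)) templateError("empty alias", i)
    if (alias %in% seen[-1] || alias == "root")
      templateError(sprintf("duplicate alias '%s'", alias), i)
    if (!method %in% TEMPLATE_METHODS)
      templateError(sprintf("unknown method '%s'", method), i)
    if (!parent %in% seen)
      templateError(sprintf("orphan parent '%s'", parent), i)
    if (method %in% c("mindensity") && length(dims) != 1)
      templateError("mindensity requires exactly one dim", i)
    if (method %in% c("quadrant", "rect", "singlet") && length(dims) != 2)
      templateError(sprintf("%s requires exactly two dims", method), i)
    signs <- strsplit(sign, "")[[1]]
    if (method %in% c("mindensity", "quadrant")) {
      if (length(signs) != length(dims) || !all(signs %in% c("+", "-")))
        templateError("sign must give one +/- per dim", i)
    }
    rows[[i]] <- list(alias = alias, parent = parent, dims = dims,
                      method = method, sign = signs, args = args)
    seen <- c(seen, alias)
  }
  new("GatingTemplate", rows = rows)
}

#' @describeIn accessors aliases of a GatingTemplate, in template order.
#' @export
setMethod("channels", "GatingTemplate", function(x) {
  unique(unlist(lapply(x@rows, `[[`, "dims")))
})

templateAliases <- function(t) vapply(t@rows, `[[`, "", "alias")

setMethod("show", "GatingTemplate", function(object) {
  cat("GatingTemplate with", length(object@rows), "rows\n")
  for (r in object@rows)
    cat(sprintf("  %-20s <- %-14s %-14s [%s] %s\n", r$alias, r$parent,
                r$method, paste(r$dims, collapse = ":"),
                paste(r$sign, collapse = "")))
})

setMethod("length", "GatingTemplate", function(x) length(x@rows))
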