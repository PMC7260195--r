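# FCS 3.0/3.1 list-mode reader and FCS 3.1 float writer.
#
# Supports $DATATYPE F (float32), D (float64) and I (uniform 16- or 32-bit
# integers), $MODE L, little- or big-endian $BYTEORD. Channel names prefer
# $PnS (stain name) over $PnN (short name). This covers what cytometer
# vendors emit for list-mode data; FCS 2.0 and log-amplifier keywords are
# out of scope.

readFcsText <- function(raw, begin, end) {
  if (end > length(raw) || begin >= end)
    formatError("TEXT segment offsets out of range; file truncated?")
  delim <- rawToChar(raw[begin])
  txt <- rawToChar(raw[(begin + 1):end])
  parts <- strsplit(txt, delim, fixed = TRUE)[[1]]
  parts <- parts[seq_len(length(parts) - length(parts) %% 2)]
  if (length(parts) < 2) formatError("empty TEXT segment")
  keys <- toupper(parts[seq(1, length(parts), by = 2)])
  vals <- trimws(parts[seq(2, length(parts), by = 2)])
  stats::setNames(as.list(vals), trimws(keys))
}

#' Read an FCS 3.0/3.1 file
#'
#' Parses the HEADER and TEXT segments, reads the list-mode DATA segment and
#' returns an [EventMatrix-class]. Channel names are taken from `$PnS` when
#' present, falling back to `$PnN`; `$DATE` and `$CYT` are carried into the
#' metadata. All channels start in `"linear"` transform state. Rows
#' containing NaN are dropped and counted.
#'
#' @param path path to an FCS file.
#' @return An [EventMatrix-class].
#' @seealso [writeFCS()], [readEventsCSV()]
#' @export
readFCS <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 58) formatError("file too short to hold an FCS header")
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    formatError(sprintf("unsupported FCS version '%s'", version))
  offs <- suppressWarnings(as.numeric(vapply(0:3, function(i) {
    rawToChar(raw[(11 + i * 8):(18 + i * 8)])
  }, "")))
  if (anyNA(offs)) formatError("malformed header offsets")
  kw <- readFcsText(raw, offs[1] + 1, offs[2] + 1)

  need <- function(k) {
    v <- kw[[k]]
    if (is.null(v)) formatError("required keyword missing", k)
    v
  }
  if (need("$MODE") != "L") formatError("only list mode is supported", "$MODE")
  dtype <- need("$DATATYPE")
  if (!dtype %in% c("F", "D", "I"))
    formatError(sprintf("unsupported data type '%s'", dtype), "$DATATYPE")
  byteord <- need("$BYTEORD")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   formatError(sprintf("unsupported byte order '%s'", byteord),
                               "$BYTEORD"))
  p <- as.integer(need("$PAR"))
  n <- as.integer(need("$TOT"))
  if (is.na(p) || p < 1) formatError("invalid parameter count", "$PAR")
  if (is.na(n) || n < 1) formatError("invalid event count", "$TOT")

  bits <- as.integer(vapply(seq_len(p), function(i) need(sprintf("$P%dB", i)), ""))
  if (dtype == "F" && !all(bits == 32)) formatError("float data requires $PnB=32", "$PnB")
  if (dtype == "D" && !all(bits == 64)) formatError("double data requires $PnB=64", "$PnB")
  if (dtype == "I" && (length(unique(bits)) != 1 || !bits[1] %in% c(16L, 32L)))
    formatError("integer data requires uniform $PnB of 16 or 32", "$PnB")

  dataBegin <- offs[3]
  dataEnd <- offs[4]
  if (dataBegin == 0 && !is.null(kw[["$BEGINDATA"]])) {
    dataBegin <- as.numeric(kw[["$BEGINDATA"]])
    dataEnd <- as.numeric(kw[["$ENDDATA"]])
  }
  size <- bits[1] / 8
  nvals <- n * p
  if (dataBegin + nvals * size - 1 > length(raw))
    formatError("DATA segment extends past end of file; file truncated?")
  con <- rawConnection(raw[(dataBegin + 1):length(raw)])
  on.exit(close(con))
  what <- if (dtype == "I") "integer" else "numeric"
  vals <- readBin(con, what, n = nvals, size = size, endian = endian,
                  signed = !(dtype == "I" && size == 2))
  if (length(vals) < nvals) formatError("DATA segment truncated")
  if (dtype == "I" && size == 2) vals[vals < 0] <- vals[vals < 0] + 65536

  chans <- vapply(seq_len(p), function(i) {
    s <- kw[[sprintf("$P%dS", i)]]
    if (!is.null(s) && nzchar(s)) s else need(sprintf("$P%dN", i))
  }, "")
  meta <- list()
  for (k in c("$DATE", "$CYT")) if (!is.null(kw[[k]]))
    meta[[sub("^\\$", "", k)]] <- kw[[k]]

  mat <- matrix(as.numeric(vals), nrow = n, ncol = p, byrow = TRUE,
                dimnames = list(NULL, chans))
  EventMatrix(mat, sampleId = sub("\\.fcs$", "", basename(path),
                                  ignore.case = TRUE),
              metadata = meta)
}

#' Write an EventMatrix as an FCS 3.1 file
#'
#' Emits single-precision float list-mode data (`$DATATYPE F`,
#' little-endian). Intended for fixtures and data exchange; values are
#' stored at float32 precision.
#'
#' @param x an [EventMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFCS <- function(x, path) {
  d <- eventData(x)
  n <- nrow(d); p <- ncol(d)
  delim <- "/"
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "0000000000", "$ENDDATA", "0000000000",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n))
  for (i in seq_len(p)) {
    kv <- c(kv, sprintf("$P%dB", i), "32", sprintf("$P%dE", i), "0,0",
            sprintf("$P%dN", i), colnames(d)[i],
            sprintf("$P%dR", i), format(ceiling(max(d[, i], 1)), scientific = FALSE))
  }
  md <- x@metadata
  if (!is.null(md$DATE)) kv <- c(kv, "$DATE", md$DATE)
  if (!is.null(md$CYT)) kv <- c(kv, "$CYT", md$CYT)

  # fixed-width zero-padded offsets keep the TEXT length independent of the
  # final values, so a single pass suffices
  text <- paste0(delim, paste(kv, collapse = delim), delim)
  textStart <- 58
  textEnd <- textStart + nchar(text) - 1
  dataStart <- textEnd + 1
  dataEnd <- dataStart + 4 * n * p - 1
  text <- sub("0000000000", sprintf("%010d", dataStart), text, fixed = TRUE)
  text <- sub("0000000000", sprintf("%010d", dataEnd), text, fixed = TRUE)

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    textStart, textEnd, dataStart, dataEnd, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(d)), con, size = 4, endian = "little")
  invisible(path)
}
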