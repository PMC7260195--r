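# The full per-population comparison battery, rendered as machine-readable
# CSV and a Markdown summary. Populations whose statistics are undefined
# (constant values, too few pairs) are reported with a reason code rather
# than dropped.

reportRow <- function(pop, pairs, masks, design, seed) {
  row <- data.frame(population = pop, n = nrow(pairs),
                    r = NA_real_, r_lo = NA_real_, r_hi = NA_real_,
                    percent_bias = NA_real_, bias_lo = NA_real_, bias_hi = NA_real_,
                    mean_diff = NA_real_, mean_abs_diff = NA_real_,
                    f_measure = NA_real_,
                    n_outliers_removed = NA_integer_,
                    r_after_outlier_removal = NA_real_,
                    icc = NA_real_, var_inter = NA_real_, var_intra = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  reasons <- character()
  tryOr <- function(expr, code) {
    tryCatch(expr, cytoError = function(e) {
      reasons <<- union(reasons, code); NULL
    })
  }
  ci <- tryOr(pearsonCI(pairs), "undefined_correlation")
  if (!is.null(ci)) { row$r <- ci["r"]; row$r_lo <- ci["lo"]; row$r_hi <- ci["hi"] }
  pb <- tryOr(percentBias(pairs, seed = seed), "undefined_bias")
  if (!is.null(pb)) {
    row$percent_bias <- pb["bias"]; row$bias_lo <- pb["lo"]; row$bias_hi <- pb["hi"]
  }
  ad <- absoluteDifference(pairs)
  row$mean_diff <- ad["mean_diff"]; row$mean_abs_diff <- ad["mean_abs_diff"]
  if (!is.null(masks[[pop]]))
    row$f_measure <- fMeasure(masks[[pop]]$hybrid, masks[[pop]]$manual)
  flt <- tryOr(removeOutliers(pairs), "too_few_for_outlier_screen")
  if (!is.null(flt)) {
    row$n_outliers_removed <- flt$nRemoved
    ci2 <- tryOr(pearsonCI(flt$pairs), "undefined_correlation_after_removal")
    if (!is.null(ci2)) row$r_after_outlier_removal <- ci2["r"]
  }
  if (!is.null(design)) {
    icc <- tryOr(iccMixedModel(design, population = pop), "icc_not_identifiable")
    if (!is.null(icc)) {
      row$icc <- icc["icc"]; row$var_inter <- icc["var_inter"]
      row$var_intra <- icc["var_intra"]
    }
  }
  if (length(reasons)) row$reason <- paste(reasons, collapse = "|")
  row
}

#' Build the per-population method-comparison report
#'
#' Runs the whole battery for every population present in `paired`:
#' Pearson r with 95% CI, percent bias with bootstrap CI, signed and
#' absolute mean difference, event-level F-measure (when masks are
#' supplied), the 3-SD outlier sensitivity re-correlation, and the
#' technician ICC (when a variability design is supplied).
#'
#' @param paired data.frame with columns `sample_id`, `population`,
#'   `hybrid`, `manual` (paired values per sample and population).
#' @param masks optional named list (by population) of
#'   `list(hybrid = <mask>, manual = <mask>)` event masks for the
#'   F-measure.
#' @param design optional technician variability design (see
#'   [iccMixedModel()]).
#' @param seed seed for the bias bootstrap.
#' @return A `ComparisonReport` data.frame, one row per population, with a
#'   `reason` column coding any undefined statistics.
#' @seealso [writeReport()]
#' @export
buildReport <- function(paired, masks = NULL, design = NULL, seed = 1L) {
  need <- c("sample_id", "population", "hybrid", "manual")
  if (!all(need %in% names(paired)))
    preconditionError(paste("paired counts must have columns",
                            paste(need, collapse = ", ")))
  pops <- unique(paired$population)
  if (!length(pops)) preconditionError("no populations in paired counts")
  out <- do.call(rbind, lapply(pops, function(pop) {
    reportRow(pop, paired[paired$population == pop, , drop = FALSE],
              masks, design, seed)
  }))
  rownames(out) <- NULL
  class(out) <- c("ComparisonReport", "data.frame")
  out
}

#' Write a comparison report as CSV and Markdown
#'
#' The CSV round-trips the numbers exactly (full precision, `#` metadata
#' header); the Markdown file renders one table of the correlation/bias
#' battery and one of the variance components, mirroring a
#' figure-and-table style summary.
#'
#' @param report a `ComparisonReport` from [buildReport()].
#' @param csvPath,mdPath output paths (`NULL` to skip one of the two).
#' @param seed seed recorded in the CSV metadata block.
#' @return Invisible list of the paths written.
#' @export
writeReport <- function(report, csvPath = NULL, mdPath = NULL, seed = NA) {
  if (!is.null(csvPath))
    writeTableWithHeader(as.data.frame(report), csvPath, seed = seed)
  if (!is.null(mdPath)) {
    fmt <- function(x, d = 3) ifelse(is.na(x), "-", formatC(x, digits = d, format = "f"))
    lines <- c("# Hybrid vs manual comparison report", "",
               sprintf("Generated by cytoHybrid %s", toolVersion()), "",
               "## Correlation, bias and agreement", "",
               "| population | n | r (95% CI) | percent bias (95% CI) | mean |diff| | F | outliers removed | r after removal |",
               "|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(report))) {
      r <- report[i, ]
      lines <- c(lines, sprintf(
        "| %s | %d | %s (%s, %s) | %s (%s, %s) | %s | %s | %s | %s |",
        r$population, r$n, fmt(r$r), fmt(r$r_lo), fmt(r$r_hi),
        fmt(r$percent_bias, 2), fmt(r$bias_lo, 2), fmt(r$bias_hi, 2),
        fmt(r$mean_abs_diff), fmt(r$f_measure),
        ifelse(is.na(r$n_outliers_removed), "-", r$n_outliers_removed),
        fmt(r$r_after_outlier_removal)))
    }
    if (any(!is.na(report$icc))) {
      lines <- c(lines, "", "## Technician variance components", "",
                 "| population | inter-technician var | intra-technician var | ICC |",
                 "|---|---|---|---|")
      for (i in seq_len(nrow(report))) {
        r <- report[i, ]
        if (is.na(r$icc)) next
        lines <- c(lines, sprintf("| %s | %s | %s | %s |", r$population,
                                  format(r$var_inter, digits = 3),
                                  format(r$var_intra, digits = 3),
                                  fmt(r$icc)))
      }
    }
    bad <- report[!is.na(report$reason), ]
    if (nrow(bad)) {
      lines <- c(lines, "", "## Populations with undefined statistics", "")
      lines <- c(lines, sprintf("- %s: %s", bad$population, bad$reason))
    }
    writeLines(lines, mdPath)
  }
  invisible(list(csv = csvPath, md = mdPath))
}
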