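# Per-gate review images. One small raster per (sample, gate) so an
# analyst can page through a batch instantly; filenames are deterministic
# (<sample_id>__<alias>.png) and re-runs overwrite in place.

plotGatePanel <- function(d, pm, node, title) {
  dims <- node@dims
  geom <- node@geometry
  if (length(dims) >= 2 && all(dims %in% colnames(d))) {
    x <- d[pm, dims[1]]; y <- d[pm, dims[2]]
    if (length(x) > 50000) {
      graphics::smoothScatter(x, y, xlab = dims[1], ylab = dims[2], main = title,
                              nrpoints = 0)
    } else {
      graphics::plot(x, y, pch = ".", col = grDevices::rgb(0, 0, 0.5, 0.3),
                     xlab = dims[1], ylab = dims[2], main = title)
    }
    if (node@kind == "quadrant") {
      graphics::abline(v = geom$cx, h = geom$cy, col = "red")
    } else if (node@kind == "rect") {
      graphics::rect(geom$x1, geom$y1, geom$x2, geom$y2, border = "red")
    } else if (node@kind == "singlet") {
      graphics::abline(0, geom$slope, col = "red")
      graphics::abline(geom$band, geom$slope, col = "red", lty = 2)
      graphics::abline(-geom$band, geom$slope, col = "red", lty = 2)
    }
  } else if (length(dims) >= 1 && dims[1] %in% colnames(d)) {
    v <- d[pm, dims[1]]
    if (length(v) >= 2) {
      graphics::plot(stats::density(v), main = title, xlab = dims[1])
    } else {
      graphics::plot.new(); graphics::title(main = title)
    }
    if (!is.null(geom$cut)) graphics::abline(v = geom$cut, col = "red")
  } else {
    graphics::plot.new(); graphics::title(main = title)
  }
}

plotErrorPanel <- function(title, error) {
  graphics::plot.new()
  graphics::title(main = title)
  graphics::text(0.5, 0.5, paste("GATE ERROR\n", error), col = "red")
}

#' Pre-generate one review image per fitted gate
#'
#' For every population of every sample in the batch, writes a 480 x 480 px
#' PNG named `<sample_id>__<alias>.png` into `outdir`: a 2D scatter of the
#' parent population on the gate's dims with the fitted geometry overlaid
#' (a density raster when the parent exceeds 50k events), or a 1D density
#' with the cut line. Errored gates produce a placeholder image stamped
#' with the error. Re-running with the same inputs overwrites the same
#' file set.
#'
#' @param results a [GatingResult-class] or list of them.
#' @param events the matching [EventMatrix-class] or list of them (same
#'   order as `results`).
#' @param outdir output directory (created if needed).
#' @param px image width/height in pixels.
#' @return Character vector of the files written, invisibly.
#' @export
pregeneratePlots <- function(results, events, outdir, px = 480) {
  if (is(results, "GatingResult")) results <- list(results)
  if (is(events, "EventMatrix")) events <- list(events)
  stopifnot(length(results) == length(events))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (i in seq_along(results)) {
    res <- results[[i]]
    d <- eventData(events[[i]])
    masks <- c(list(root = rep(TRUE, nrow(d))),
               lapply(res@populations, function(p) p@membership))
    for (alias in names(res@nodes)) {
      node <- res@nodes[[alias]]
      file <- file.path(outdir, paste0(res@sampleId, "__", alias, ".png"))
      pm <- masks[[node@parent]] %||% rep(TRUE, nrow(d))
      grDevices::png(file, width = px, height = px)
      tryCatch({
        title <- paste0(res@sampleId, ": ", alias)
        if (!is.na(node@error)) plotErrorPanel(title, node@error)
        else plotGatePanel(d, pm, node, title)
      }, finally = grDevices::dev.off())
      written <- c(written, file)
    }
  }
  invisible(written)
}
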