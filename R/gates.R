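# Data-driven gate fitting primitives. All are deterministic for a fixed
# input: the kernel density estimate uses a fixed 512-point grid and
# Silverman's rule unless a bandwidth is given, and all ties break leftmost
# (peaks and valleys) or by fixed ordering.

DEFAULT_MIN_EVENTS <- 20

kdeGrid <- function(x, gateRange, bandwidth) {
  bw <- if (is.null(bandwidth) || identical(bandwidth, "auto"))
    stats::bw.nrd0(x) else as.numeric(bandwidth)
  if (!is.finite(bw) || bw <= 0) bw <- max(stats::sd(x) / 10, 1e-6)
  stats::density(x, bw = bw, n = 512, from = gateRange[1], to = gateRange[2])
}

findPeaks <- function(d, minPeakHeight) {
  y <- d$y
  n <- length(y)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (y[1] > y[2]) cand <- c(1L, cand)
  if (y[n] > y[n - 1]) cand <- c(cand, n)
  cand[y[cand] >= minPeakHeight * max(y)]
}

#' Place a one-dimensional density-valley cut
#'
#' Fits a Gaussian kernel density estimate to `x` restricted to
#' `gate_range`, finds local maxima whose height is at least
#' `min_peak_height` times the tallest density, and places the cut at the
#' density minimum between the two tallest peaks. With a single detectable
#' peak the cut falls where the density decays to `min_peak_height` times
#' the peak height on the side indicated by `sign` (the side where the
#' positive child population is expected). Zero surviving peaks raise a gate
#' error tagged `"needs_manual_refinement"`; fewer than `minEvents` events
#' raise one tagged `"low_cell_count"`.
#'
#' @param x numeric vector of events on one (transformed) channel.
#' @param sign `"+"` or `"-"`: side of the cut the child population lies on.
#' @param gateRange length-2 numeric: the approximate range in the data
#'   where the gate should be placed; defaults to the data range.
#' @param minPeakHeight peak-detection sensitivity threshold, as a fraction
#'   of the maximum density.
#' @param expectedPeaks optional expected number of populations (1 forces
#'   the single-peak shoulder rule even when two peaks are visible).
#' @param bandwidth KDE bandwidth, or `"auto"` for Silverman's rule.
#' @param minEvents minimum events required to fit a gate.
#' @return The cut point (numeric scalar) with attribute `"peaks"` (grid
#'   positions of the detected peaks).
#' @examples
#' x <- c(rnorm(500, 0, 0.2), rnorm(500, 4, 0.2))
#' densityCut1d(x, "+")  # valley near 2
#' @export
densityCut1d <- function(x, sign = "+", gateRange = NULL,
                         minPeakHeight = 0.05, expectedPeaks = NULL,
                         bandwidth = NULL, minEvents = DEFAULT_MIN_EVENTS) {
  if (length(x) < minEvents)
    gateError(sprintf("only %d events (< %d) available for density gate",
                      length(x), minEvents), tag = "low_cell_count")
  if (is.null(gateRange)) gateRange <- range(x)
  xr <- x[x >= gateRange[1] & x <= gateRange[2]]
  if (length(xr) < minEvents)
    gateError("too few events inside gate_range", tag = "low_cell_count")
  d <- kdeGrid(xr, gateRange, bandwidth)
  peaks <- findPeaks(d, minPeakHeight)
  if (length(peaks) == 0)
    gateError("no density peaks above the sensitivity threshold")
  single <- length(peaks) == 1 ||
    (!is.null(expectedPeaks) && expectedPeaks == 1)
  if (!single) {
    # two tallest peaks; equal heights resolve to the leftmost pair
    ord <- order(-d$y[peaks], peaks)
    top2 <- sort(peaks[ord[1:2]])
    between <- seq(top2[1], top2[2])
    valley <- between[which.min(d$y[between])]
    cut <- d$x[valley]
  } else {
    pk <- peaks[which.max(d$y[peaks])]
    thr <- minPeakHeight * d$y[pk]
    idx <- if (identical(sign, "+")) seq(pk, length(d$y)) else seq(pk, 1)
    below <- idx[d$y[idx] <= thr]
    cut <- if (length(below)) d$x[below[1]] else
      d$x[idx[length(idx)]]  # never decays below threshold: cut at range edge
  }
  structure(cut, peaks = d$x[peaks])
}

#' Fit a quadrant gate
#'
#' Places independent 1D density cuts on each axis (see [densityCut1d()])
#' and partitions the events into the four sign quadrants around the
#' resulting centre; `x+` means strictly greater than the cut, `x-` means
#' less than or equal, so the four quadrants partition the input exactly.
#'
#' @param x,y numeric event vectors of equal length.
#' @param signX,signY which side of each axis the child population of
#'   interest lies on (used by [applyTemplate()] to pick a quadrant).
#' @param gateRangeX,gateRangeY per-axis gate ranges.
#' @param ... further arguments passed to [densityCut1d()] (bandwidth,
#'   `minPeakHeight`, ...).
#' @return List with `cx`, `cy`, and `quadrants`: a named list of the four
#'   logical masks `"++"`, `"+-"`, `"-+"`, `"--"` (x sign first).
#' @export
quadrantGate <- function(x, y, signX = "+", signY = "+",
                         gateRangeX = NULL, gateRangeY = NULL, ...) {
  cx <- as.numeric(densityCut1d(x, sign = signX, gateRange = gateRangeX, ...))
  cy <- as.numeric(densityCut1d(y, sign = signY, gateRange = gateRangeY, ...))
  xp <- x > cx
  yp <- y > cy
  list(cx = cx, cy = cy,
       quadrants = list("++" = xp & yp, "+-" = xp & !yp,
                        "-+" = !xp & yp, "--" = !xp & !yp))
}

#' Singlet (doublet-exclusion) gate on FSC-A/FSC-H
#'
#' Doublets record roughly additive forward-scatter area but sub-additive
#' height, so they fall below the FSC-H ~ FSC-A line formed by singlets.
#' The gate fits a robust through-origin line `h = beta * a` with
#' `beta = median(h/a)` and keeps events whose residual lies within
#' `bandK` MADs.
#'
#' @param a FSC-A values.
#' @param h FSC-H values (same length).
#' @param bandK half-width of the acceptance band in residual MAD units.
#' @param minEvents minimum events required.
#' @return Logical membership mask with attributes `"slope"` and `"band"`
#'   (the absolute residual half-width).
#' @export
singletGate <- function(a, h, bandK = 4, minEvents = DEFAULT_MIN_EVENTS) {
  if (length(a) != length(h)) preconditionError("FSC-A and FSC-H lengths differ")
  if (length(a) < minEvents)
    gateError(sprintf("only %d events (< %d) for singlet gate", length(a), minEvents),
              tag = "low_cell_count")
  ok <- a != 0
  if (!any(ok)) gateError("degenerate scatter: all FSC-A values are zero")
  beta <- stats::median(h[ok] / a[ok])
  res <- h - beta * a
  s <- stats::mad(res)
  if (s == 0) s <- max(abs(res)) * 1e-6 + 1e-12  # exact-line degenerate case
  keep <- abs(res) <= bandK * s
  structure(keep, slope = beta, band = bandK * s)
}
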