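# Fluorescence transforms. Gating operates in transformed coordinates where
# negative and positive populations are roughly Gaussian; the raw
# (amplifier) scale compresses the negatives against zero.

#' Fluorescence transforms for cytometry channels
#'
#' `arcsinhTransform()` returns the inverse hyperbolic sine transform
#' `asinh(x / cofactor)`; cofactor 150 is a common choice for conventional
#' (non-mass) cytometers. `logicleTransform()` returns the biexponential
#' logicle transform of Parks, Roederer and Moore, parameterised by the top
#' of scale `T`, linearisation width `W` (decades), total display range `M`
#' (decades) and additional negative range `A`; values are returned in
#' decade units on `[A-ish, M]`. `linearTransform()` is the identity. All
#' transforms are strictly increasing.
#'
#' @param cofactor arcsinh cofactor (same units as the raw data).
#' @param T top of the data scale, e.g. 262144 for an 18-bit digitiser.
#' @param W linearisation width in decades (> 0).
#' @param M number of decades the transform spans.
#' @param A additional decades of negative range.
#' @return A `cytoTransform` object: a list with elements `type`, `label`
#'   and the vectorised function `fun`.
#' @examples
#' tr <- arcsinhTransform(150)
#' tr$fun(150)  # asinh(1)
#' @export
arcsinhTransform <- function(cofactor = 150) {
  structure(list(type = "arcsinh",
                 label = sprintf("arcsinh(cofactor=%g)", cofactor),
                 fun = function(x) asinh(x / cofactor),
                 inverse = function(y) sinh(y) * cofactor),
            class = "cytoTransform")
}

#' @rdname arcsinhTransform
#' @export
linearTransform <- function() {
  structure(list(type = "linear", label = "linear", fun = identity,
                 inverse = identity),
            class = "cytoTransform")
}

#' @rdname arcsinhTransform
#' @export
logicleTransform <- function(T = 262144, W = 0.5, M = 4.5, A = 0) {
  if (W <= 0 || M <= 0 || T <= 0) preconditionError("logicle requires T, W, M > 0")
  w <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b <- (M + A) * log(10)
  # d solves 2(ln d - ln b) + w(b + d) = 0 on (0, b)
  d <- stats::uniroot(function(d) 2 * (log(d) - log(b)) + w * (b + d),
                      c(1e-10, b), tol = 1e-12)$root
  ca <- exp(x0 * (b + d))
  fa <- exp(b * x1) - ca * exp(-d * x1)
  a <- T / (exp(b) - ca * exp(-d) - fa)
  cc <- ca * a
  f <- fa * a
  fwd <- function(x) a * exp(b * x) - cc * exp(-d * x) - f  # strictly increasing
  # dense near the display range, sparser in the far tails so the numeric
  # inverse stays strictly monotone over any realistic data range
  grid <- sort(unique(c(seq(-3, 3, length.out = 2048),
                        seq(-0.5, 1.5, length.out = 8192))))
  inv <- stats::splinefun(fwd(grid), grid, method = "hyman")
  structure(list(type = "logicle",
                 label = sprintf("logicle(T=%g,W=%g,M=%g,A=%g)", T, W, M, A),
                 fun = function(x) inv(pmin(pmax(x, fwd(-3)), fwd(3))) * (M + A),
                 inverse = function(y) fwd(y / (M + A))),
            class = "cytoTransform")
}

isScatterChannel <- function(ch) grepl("^(FSC|SSC)", ch) | ch == "Time"

#' Channels conventionally transformed before gating
#'
#' All channels of `x` except forward/side scatter and Time.
#'
#' @param x an [EventMatrix-class].
#' @return Character vector of fluorescence channel names.
#' @export
fluorescenceChannels <- function(x) {
  ch <- channels(x)
  ch[!isScatterChannel(ch)]
}

#' Apply per-channel transforms to an EventMatrix
#'
#' `spec` is either a single `cytoTransform` — applied to every fluorescence
#' channel, leaving scatter (FSC*/SSC*) and Time linear — or a named list of
#' `cytoTransform` objects applied exactly to the named channels (which may
#' include scatter channels when named explicitly). The per-channel
#' `transformState` labels are updated accordingly.
#'
#' @param x an [EventMatrix-class].
#' @param spec a `cytoTransform` or a named list of them.
#' @return A transformed [EventMatrix-class].
#' @examples
#' em <- EventMatrix(matrix(c(0, 150), 2, 1, dimnames = list(NULL, "CD3")))
#' eventData(applyTransform(em, arcsinhTransform(150)))
#' @export
applyTransform <- function(x, spec) {
  if (inherits(spec, "cytoTransform")) {
    spec <- stats::setNames(rep(list(spec), length(fluorescenceChannels(x))),
                            fluorescenceChannels(x))
  }
  if (!length(spec)) return(x)
  unknown <- setdiff(names(spec), channels(x))
  if (length(unknown))
    preconditionError(paste("unknown channel(s) in transform spec:",
                            paste(unknown, collapse = ", ")))
  d <- eventData(x)
  ts <- transformState(x)
  for (ch in names(spec)) {
    tr <- spec[[ch]]
    if (!inherits(tr, "cytoTransform"))
      preconditionError(sprintf("transform for channel '%s' is not a cytoTransform", ch))
    d[, ch] <- tr$fun(d[, ch])
    ts[ch] <- tr$label
  }
  initialize(x, data = d, transformState = ts)
}
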