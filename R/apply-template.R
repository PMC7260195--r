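# Hierarchical template application. A single gate failure never aborts the
# sample: the offending node records the error and its subtree is tagged,
# mirroring the flag-for-manual hand-off of a hybrid workflow.

newPopulation <- function(alias, parent, mask, parentCount, nTotal, wbc,
                          flags = character()) {
  count <- sum(mask)
  pctParent <- if (parentCount > 0) 100 * count / parentCount else {
    flags <- union(flags, "low_cell_count"); 0
  }
  pctTotal <- 100 * count / nTotal
  new("PopulationResult", alias = alias, parent = parent, membership = mask,
      count = as.integer(count), pctOfParent = pctParent,
      pctOfTotal = pctTotal,
      absCount = if (is.null(wbc)) NA_real_ else pctTotal / 100 * wbc,
      flags = flags)
}

erroredPopulation <- function(alias, parent, n, tag, lowCell = FALSE) {
  new("PopulationResult", alias = alias, parent = parent,
      membership = rep(FALSE, n),
      count = if (lowCell) 0L else NA_integer_,
      pctOfParent = if (lowCell) 0 else NA_real_,
      pctOfTotal = if (lowCell) 0 else NA_real_,
      absCount = NA_real_, flags = tag)
}

rowArg <- function(args, name, default = NULL) args[[name]] %||% default

#' Apply a gating template to a sample
#'
#' Evaluates the template rows in order against the events of `x`: the root
#' population is all retained events, each child's membership is
#' intersected with its parent's, and each data-driven gate (density cut,
#' quadrant, rectangle, singlet band, boolean combination) is fitted on the
#' parent's events only. `kmeans_subsets` rows delegate to the three-marker
#' k-means subset caller ([callSubsets()]) and emit one population per
#' parent x subset. Gate failures tag the population (and its subtree) with
#' an annotation-vocabulary flag instead of aborting; populations under an
#' empty parent get zero counts and a `"low_cell_count"` flag.
#'
#' @param x an [EventMatrix-class] (typically transformed, see
#'   [applyTransform()]; `gate_range` args are interpreted on the
#'   transformed scale).
#' @param template a [GatingTemplate-class].
#' @param wbc optional white-blood-cell count (10^9 cells/L) for this
#'   sample; absolute counts are percent-of-total x WBC.
#' @param minEvents minimum parent events required to fit a data-driven
#'   gate (populations below it are flagged `"low_cell_count"`).
#' @return A [GatingResult-class] with per-population results and fitted
#'   gate geometry.
#' @seealso [parseGatingTemplate()], [exportGatesJSON()], [countsTable()]
#' @export
applyTemplate <- function(x, template, wbc = NULL,
                          minEvents = DEFAULT_MIN_EVENTS) {
  stopifnot(is(x, "EventMatrix"), is(template, "GatingTemplate"))
  missingDims <- setdiff(channels(template), channels(x))
  kmRows <- vapply(template@rows, function(r) r$method == "kmeans_subsets", TRUE)
  missingDims <- setdiff(missingDims,
                         unlist(lapply(template@rows[kmRows], `[[`, "dims")))
  if (length(missingDims))
    preconditionError(paste("template dims absent from sample:",
                            paste(missingDims, collapse = ", ")))
  d <- eventData(x)
  n <- nrow(d)
  masks <- list(root = rep(TRUE, n))
  pops <- list()
  nodes <- list()
  failedTag <- list()  # alias -> tag for errored nodes

  addNode <- function(alias, parent, kind, dims, geometry, error = NA_character_) {
    nodes[[alias]] <<- new("GateNode", alias = alias, parent = parent,
                           kind = kind, dims = dims, geometry = geometry,
                           error = error)
  }

  for (r in template@rows) {
    alias <- r$alias; parent <- r$parent
    pm <- masks[[parent]]
    parentFailed <- !is.null(failedTag[[parent]])
    if (parentFailed) {
      tag <- failedTag[[parent]]
      pops[[alias]] <- erroredPopulation(alias, parent, n, tag,
                                         lowCell = tag == "low_cell_count")
      addNode(alias, parent, r$method, r$dims, list(), error = "parent gate failed")
      failedTag[[alias]] <- tag
      masks[[alias]] <- rep(FALSE, n)
      next
    }
    pc <- sum(pm)
    res <- tryCatch({
      switch(r$method,
        mindensity = {
          v <- d[pm, r$dims[1]]
          cut <- densityCut1d(v, sign = r$sign[1],
                              gateRange = rowArg(r$args, "gate_range"),
                              minPeakHeight = rowArg(r$args, "min_peak_height", 0.05),
                              expectedPeaks = rowArg(r$args, "expected_peaks"),
                              bandwidth = rowArg(r$args, "bandwidth"),
                              minEvents = minEvents)
          side <- if (r$sign[1] == "+") d[, r$dims[1]] > as.numeric(cut)
                  else d[, r$dims[1]] <= as.numeric(cut)
          list(mask = pm & side, geom = list(cut = as.numeric(cut)))
        },
        quadrant = {
          qg <- quadrantGate(d[pm, r$dims[1]], d[pm, r$dims[2]],
                             signX = r$sign[1], signY = r$sign[2],
                             gateRangeX = rowArg(r$args, "gate_range_x",
                                                 rowArg(r$args, "gate_range")),
                             gateRangeY = rowArg(r$args, "gate_range_y",
                                                 rowArg(r$args, "gate_range")),
                             minPeakHeight = rowArg(r$args, "min_peak_height", 0.05),
                             bandwidth = rowArg(r$args, "bandwidth"),
                             minEvents = minEvents)
          xp <- if (r$sign[1] == "+") d[, r$dims[1]] > qg$cx else d[, r$dims[1]] <= qg$cx
          yp <- if (r$sign[2] == "+") d[, r$dims[2]] > qg$cy else d[, r$dims[2]] <= qg$cy
          list(mask = pm & xp & yp,
               geom = list(cx = qg$cx, cy = qg$cy,
                           quadrant = paste(r$sign, collapse = "")))
        },
        rect = {
          b <- rowArg(r$args, "bounds")
          if (is.null(b) || length(b) != 4)
            gateError("rect gate requires args bounds=[x1,x2,y1,y2]")
          inside <- d[, r$dims[1]] >= b[1] & d[, r$dims[1]] <= b[2] &
                    d[, r$dims[2]] >= b[3] & d[, r$dims[2]] <= b[4]
          list(mask = pm & inside,
               geom = list(x1 = b[1], x2 = b[2], y1 = b[3], y2 = b[4]))
        },
        singlet = {
          keep <- singletGate(d[pm, r$dims[1]], d[pm, r$dims[2]],
                              bandK = rowArg(r$args, "band_k", 4),
                              minEvents = minEvents)
          mask <- rep(FALSE, n)
          mask[which(pm)[keep]] <- TRUE
          list(mask = mask,
               geom = list(slope = attr(keep, "slope"), band = attr(keep, "band")))
        },
        boolean = {
          expr <- rowArg(r$args, "expr")
          if (is.null(expr)) gateError("boolean gate requires args expr=...")
          refs <- all.vars(parse(text = expr))
          if (!all(refs %in% names(masks)))
            gateError(paste("boolean gate references unknown alias:",
                            paste(setdiff(refs, names(masks)), collapse = ", ")))
          val <- eval(parse(text = expr), envir = masks)
          list(mask = pm & val, geom = list(expr = expr))
        },
        kmeans_subsets = {
          applyKmeansSubsetsRow(r, d, masks, pm, n)
        })
    }, cytoGateError = function(e) e)

    if (inherits(res, "cytoGateError")) {
      tag <- gateErrorTag(res)
      pops[[alias]] <- erroredPopulation(alias, parent, n, tag,
                                         lowCell = tag == "low_cell_count")
      addNode(alias, parent, r$method, r$dims, list(),
              error = conditionMessage(res))
      failedTag[[alias]] <- tag
      masks[[alias]] <- rep(FALSE, n)
      next
    }

    if (r$method == "kmeans_subsets") {
      addNode(alias, parent, r$method, r$dims, res$geom)
      masks[[alias]] <- pm
      pops[[alias]] <- newPopulation(alias, parent, pm, pc, n, wbc,
                                     flags = res$flags)
      for (ch in res$children) {
        masks[[ch$alias]] <- ch$mask
        pops[[ch$alias]] <- newPopulation(ch$alias, ch$parent, ch$mask,
                                          sum(masks[[ch$parent]]), n, wbc,
                                          flags = res$flags)
        addNode(ch$alias, ch$parent, "kmeans_subset", r$dims,
                list(subset = ch$subset))
      }
    } else {
      masks[[alias]] <- res$mask
      pops[[alias]] <- newPopulation(alias, parent, res$mask, pc, n, wbc)
      addNode(alias, parent, r$method, r$dims, res$geom)
    }
  }
  new("GatingResult", sampleId = sampleId(x), nEvents = as.integer(n),
      populations = pops, nodes = nodes)
}

# A kmeans_subsets row pools the events of the parent aliases named in
# args (parents=CD4:CD8), clusters the three markers, and emits one child
# population per parent x subset named "<parent>_<subset>".
applyKmeansSubsetsRow <- function(r, d, masks, pm, n) {
  markers <- rowArg(r$args, "markers", c("CCR7", "CD45RA", "CD28"))
  parents <- rowArg(r$args, "parents")
  seed <- as.integer(rowArg(r$args, "seed", 1))
  if (is.null(parents) || length(parents) < 1)
    gateError("kmeans_subsets requires args parents=<alias>:<alias>")
  if (!all(parents %in% names(masks)))
    gateError(paste("kmeans_subsets parent alias not gated yet:",
                    paste(setdiff(parents, names(masks)), collapse = ", ")))
  if (!all(markers %in% colnames(d)))
    gateError(paste("kmeans_subsets markers absent:",
                    paste(setdiff(markers, colnames(d)), collapse = ", ")))
  pooled <- Reduce(`|`, masks[parents])
  idx <- which(pooled)
  parentLab <- rep(NA_character_, length(idx))
  for (p in parents) parentLab[masks[[p]][idx]] <- p
  call <- tryCatch(
    callSubsets(d[idx, markers, drop = FALSE], parentLab, seed = seed,
                parents = parents),
    cytoPreconditionError = function(e) gateError(conditionMessage(e),
                                                  tag = "low_cell_count"))
  children <- list()
  for (p in parents) for (s in TSUBSET_NAMES) {
    mask <- rep(FALSE, n)
    sel <- parentLab == p & call@subsetLabels[call@assignment] == s
    mask[idx[sel]] <- TRUE
    children[[paste(p, s, sep = "_")]] <-
      list(alias = paste(p, s, sep = "_"), parent = p, subset = s, mask = mask)
  }
  list(mask = pm, children = children, call = call,
       flags = if (isFlagged(call)) "needs_manual_refinement" else character(),
       geom = list(markers = markers, parents = parents, seed = seed,
                   flagged = isFlagged(call)))
}
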