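# Synthetic event-cloud generator. Emulates the statistical structure the
# gating pipeline assumes -- a population hierarchy of Gaussian components
# in transformed (arcsinh) fluorescence space plus linear scatter, with
# doublets, dead cells and ground-truth labels -- so every module is
# testable without instrument data. It does not model spillover,
# autofluorescence or instrument drift.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Marker sign table for the four memory/effector subsets in
# (CCR7, CD45RA, CD28) order; the CCR7/CD45RA pair defines the subset and
# CD28 follows the canonical phenotype (naive CD28+, effector CD28-).
SUBSET_SIGNS <- rbind(naive           = c(+1, +1, +1),
                      central_memory  = c(+1, -1, +1),
                      effector_memory = c(-1, -1, -1),
                      effector        = c(-1, +1, -1))
colnames(SUBSET_SIGNS) <- c("CCR7", "CD45RA", "CD28")

POS_MEAN <- 3.5; NEG_MEAN <- 0.5; FLUOR_SD <- 0.35

#' Default synthetic panel specification
#'
#' A population hierarchy mirroring a standard immunophenotyping panel:
#' debris plus live cells splitting into lymphocytes (T cells with CD4/CD8
#' parents and their four memory/effector subsets, B cells, NK cells),
#' monocytes and dendritic cells, over channels FSC-A/FSC-H/SSC-A, a
#' live-dead stain, and the lineage/subset markers. Fluorescence components
#' are Gaussians in arcsinh-transformed units (negative mean 0.5, positive
#' mean 3.5, SD 0.35); scatter is linear. Sibling fractions are fractions
#' of the parent; any remainder becomes an `<parent>_other` leaf.
#'
#' @param nEvents events per sample (default 20,000, a common per-file
#'   inclusion floor).
#' @param doubletFraction fraction of events synthesised as doublets
#'   (FSC-A adds, FSC-H sub-additive at 0.6 of the sum).
#' @param deadFraction fraction of cells given a high live-dead signal.
#' @return A `PanelSpec` list (channels, populations, baseline, fractions).
#' @seealso [generateSample()]
#' @export
defaultPanelSpec <- function(nEvents = 20000, doubletFraction = 0.03,
                             deadFraction = 0.05) {
  pos <- c(POS_MEAN, FLUOR_SD)
  popn <- function(alias, parent, fraction, channels = list())
    list(alias = alias, parent = parent, fraction = fraction, channels = channels)
  subsets <- function(parentAlias) {
    fr <- c(naive = 0.40, central_memory = 0.25, effector_memory = 0.25,
            effector = 0.10)
    lapply(names(fr), function(s) {
      ch <- lapply(seq_len(3), function(j)
        c(if (SUBSET_SIGNS[s, j] > 0) POS_MEAN else NEG_MEAN, FLUOR_SD))
      names(ch) <- colnames(SUBSET_SIGNS)
      popn(paste(parentAlias, s, sep = "_"), parentAlias, fr[[s]], ch)
    })
  }
  populations <- c(list(
    popn("debris", "root", 0.08,
         list(`FSC-A` = c(25000, 6000), `SSC-A` = c(12000, 5000))),
    popn("lymphocytes", "root", 0.60,
         list(`FSC-A` = c(75000, 7000), `SSC-A` = c(30000, 7000))),
    popn("Tcells", "lymphocytes", 0.55, list(CD3 = pos)),
    popn("CD4", "Tcells", 0.60, list(CD4 = pos)),
    popn("CD8", "Tcells", 0.35, list(CD8 = pos))),
    subsets("CD4"), subsets("CD8"), list(
    popn("Bcells", "lymphocytes", 0.15,
         list(CD19 = pos, CD20 = pos, `HLA-DR` = pos)),
    popn("NK", "lymphocytes", 0.15, list(CD16 = pos, CD56 = pos)),
    popn("monocytes", "root", 0.22,
         list(`FSC-A` = c(110000, 9000), `SSC-A` = c(80000, 9000),
              CD14 = pos, `HLA-DR` = pos)),
    popn("dendritic", "root", 0.04,
         list(`FSC-A` = c(105000, 8000), `SSC-A` = c(65000, 8000),
              `HLA-DR` = pos))))
  channels <- c("FSC-A", "FSC-H", "SSC-A", "LiveDead", "CD3", "CD19", "CD14",
                "HLA-DR", "CD16", "CD56", "CD20", "CD4", "CD8",
                "CCR7", "CD45RA", "CD28")
  baseline <- stats::setNames(rep(list(c(NEG_MEAN, FLUOR_SD)), length(channels)),
                              channels)
  # baseline scatter sits in granulocyte territory so untyped remainder
  # populations stay clear of the lymphocyte scatter gate
  baseline[["FSC-A"]] <- c(120000, 10000)
  baseline[["SSC-A"]] <- c(90000, 10000)
  baseline[["LiveDead"]] <- c(NEG_MEAN, 0.3)
  structure(list(channels = channels, populations = populations,
                 baseline = baseline, nEvents = nEvents,
                 doubletFraction = doubletFraction,
                 deadFraction = deadFraction),
            class = "PanelSpec")
}

# Resolve the tree to leaves with absolute fractions and fully inherited
# channel parameters; sibling remainders become "<parent>_other" leaves.
resolveLeaves <- function(spec) {
  pops <- spec$populations
  aliases <- vapply(pops, `[[`, "", "alias")
  if (anyDuplicated(aliases)) preconditionError("duplicate population alias in spec")
  byParent <- split(seq_along(pops), vapply(pops, `[[`, "", "parent"))
  for (p in names(byParent)) {
    fr <- vapply(pops[byParent[[p]]], `[[`, 0, "fraction")
    if (any(fr <= 0) || sum(fr) > 1 + 1e-9)
      preconditionError(sprintf("fractions of children of '%s' must be positive and sum to <= 1", p))
  }
  leaves <- list()
  walk <- function(alias, absFrac, chans, path) {
    kids <- byParent[[alias]]
    if (is.null(kids)) {
      leaves[[length(leaves) + 1]] <<- list(alias = alias, frac = absFrac,
                                            channels = chans, path = path)
      return()
    }
    s <- 0
    for (i in kids) {
      node <- pops[[i]]
      kidCh <- utils::modifyList(chans, node$channels)
      walk(node$alias, absFrac * node$fraction, kidCh,
           paste(path, node$alias, sep = "/"))
      s <- s + node$fraction
    }
    if (s < 1 - 1e-9) {
      other <- paste0(alias, "_other")
      leaves[[length(leaves) + 1]] <<- list(alias = other,
                                            frac = absFrac * (1 - s),
                                            channels = chans,
                                            path = paste(path, other, sep = "/"))
    }
  }
  walk("root", 1, spec$baseline, "root")
  leaves
}

#' Generate one synthetic sample with ground truth
#'
#' Draws events per leaf population from the spec's Gaussian components,
#' derives FSC-H from FSC-A (singlet line, slope 0.98), then synthesises
#' doublets by combining two singlets (scatter adds; FSC-H sub-additive at
#' 0.6 of the sum; fluorescence takes the pairwise maximum) and marks a
#' fraction of cells dead via a high live-dead signal. All randomness is
#' governed by `seed`.
#'
#' @param spec a `PanelSpec` (see [defaultPanelSpec()]).
#' @param seed integer seed.
#' @param sampleId sample identifier.
#' @return List with `events` (an [EventMatrix-class]; fluorescence already
#'   in transformed units), `truth` (data.frame per event: leaf
#'   `population`, full `path`, `isDoublet`, `isDead`), `fractions` (true
#'   leaf fractions among intact live cells) and `wbc` (true white-blood-cell
#'   count, 10^9 cells/L).
#' @export
generateSample <- function(spec = defaultPanelSpec(), seed = 1L,
                           sampleId = sprintf("sim%03d", seed)) {
  stopifnot(inherits(spec, "PanelSpec"))
  leaves <- resolveLeaves(spec)
  withSeed(seed, {
    n <- spec$nEvents
    fr <- vapply(leaves, `[[`, 0, "frac")
    leafIdx <- sample.int(length(leaves), n, replace = TRUE, prob = fr)
    d <- matrix(0, n, length(spec$channels),
                dimnames = list(NULL, spec$channels))
    for (i in seq_along(leaves)) {
      rows <- which(leafIdx == i)
      if (!length(rows)) next
      for (ch in spec$channels) {
        if (ch == "FSC-H") next
        p <- leaves[[i]]$channels[[ch]]
        d[rows, ch] <- stats::rnorm(length(rows), p[1], p[2])
      }
    }
    d[, "FSC-A"] <- pmax(d[, "FSC-A"], 1000)
    d[, "FSC-H"] <- 0.98 * d[, "FSC-A"] + stats::rnorm(n, 0, 1500)

    isDoublet <- rep(FALSE, n)
    nd <- round(spec$doubletFraction * n)
    if (nd > 0) {
      tgt <- sample.int(n, nd)
      prt <- sample.int(n, nd, replace = TRUE)
      scatter <- c("FSC-A", "SSC-A")
      d[tgt, scatter] <- d[tgt, scatter] + d[prt, scatter]
      d[tgt, "FSC-H"] <- 0.6 * (d[tgt, "FSC-H"] + d[prt, "FSC-H"])
      fluor <- setdiff(spec$channels, c(scatter, "FSC-H"))
      d[tgt, fluor] <- pmax(d[tgt, fluor], d[prt, fluor])
      isDoublet[tgt] <- TRUE
    }
    isDead <- rep(FALSE, n)
    ndead <- round(spec$deadFraction * n)
    if (ndead > 0) {
      dd <- sample(which(!isDoublet), ndead)
      d[dd, "LiveDead"] <- stats::rnorm(ndead, POS_MEAN, 0.4)
      isDead[dd] <- TRUE
    }
    truth <- data.frame(
      population = vapply(leaves, `[[`, "", "alias")[leafIdx],
      path = vapply(leaves, `[[`, "", "path")[leafIdx],
      isDoublet = isDoublet, isDead = isDead, stringsAsFactors = FALSE)
    clean <- !isDoublet & !isDead
    fractions <- tapply(clean, truth$population, sum) / sum(clean)
    wbc <- stats::rlnorm(1, log(6), 0.2)
    list(events = EventMatrix(d, sampleId = sampleId,
                              metadata = list(CYT = "synthetic")),
         truth = truth, fractions = fractions, wbc = wbc)
  })
}

#' Ground-truth membership mask for a gated population
#'
#' Maps a template alias onto the generator's truth labels: an intact
#' (non-doublet) live event belongs to `alias` when `alias` appears on its
#' population path. The pre-gates are special-cased: `singlets` excludes
#' doublets only, `live` also excludes dead cells, and `linNeg`
#' (lineage-negative) is live minus T/B/NK/monocytes.
#'
#' @param truth truth data.frame from [generateSample()].
#' @param alias population alias.
#' @return Logical mask over events.
#' @export
truthMask <- function(truth, alias) {
  clean <- !truth$isDoublet & !truth$isDead
  inPath <- function(a) grepl(paste0("/", a, "(/|$)"), truth$path)
  switch(alias,
    root = rep(TRUE, nrow(truth)),
    singlets = !truth$isDoublet,
    live = clean,
    linNeg = clean & !inPath("Tcells") & !inPath("Bcells") &
             !inPath("NK") & !inPath("monocytes"),
    clean & inPath(alias))
}

#' Generate a three-marker T-cell sample for the subset caller
#'
#' Four Gaussian components per parent, centred at +/- `separation / 2`
#' (in within-component SD units) in each marker dimension according to the
#' canonical CCR7/CD45RA/CD28 sign table, with per-event truth labels.
#'
#' @param fractions named subset fractions for the CD4 helper parent
#'   (must sum to 1; names as in `c("naive", "central_memory",
#'   "effector_memory", "effector")`).
#' @param fractionsCD8 subset fractions for the CD8 cytotoxic parent
#'   (defaults to `fractions`).
#' @param n total T-cell events.
#' @param cd4Fraction fraction of events in the CD4 parent.
#' @param separation component separation in SD multiples (0 = fully
#'   overlapping, unmappable by construction).
#' @param seed integer seed.
#' @return List with `markers` (n x 3 matrix, CCR7/CD45RA/CD28), `parent`
#'   (per-event "CD4"/"CD8"), and `subset` (per-event truth label).
#' @export
generateTcellSample <- function(fractions = c(naive = 0.40,
                                              central_memory = 0.25,
                                              effector_memory = 0.25,
                                              effector = 0.10),
                                fractionsCD8 = NULL, n = 20000,
                                cd4Fraction = 0.6, separation = 6,
                                seed = 1L) {
  fractionsCD8 <- fractionsCD8 %||% fractions
  for (fr in list(fractions, fractionsCD8)) {
    if (!setequal(names(fr), rownames(SUBSET_SIGNS)))
      preconditionError("fractions must be named with the four subset names")
    if (abs(sum(fr) - 1) > 1e-6)
      preconditionError("subset fractions must sum to 1")
  }
  withSeed(seed, {
    parent <- ifelse(stats::runif(n) < cd4Fraction, "CD4", "CD8")
    subset <- character(n)
    for (p in c("CD4", "CD8")) {
      sel <- parent == p
      fr <- if (p == "CD4") fractions else fractionsCD8
      subset[sel] <- sample(rownames(SUBSET_SIGNS), sum(sel), replace = TRUE,
                            prob = fr[rownames(SUBSET_SIGNS)])
    }
    centers <- SUBSET_SIGNS * separation / 2
    markers <- centers[subset, , drop = FALSE] +
      matrix(stats::rnorm(3 * n), n, 3)
    dimnames(markers) <- list(NULL, colnames(SUBSET_SIGNS))
    list(markers = markers, parent = parent, subset = subset)
  })
}

#' Generate paired hybrid/manual counts with a known bias
#'
#' Per sample and population, a true value is drawn around `true` with
#' between-sample lognormal variation, and each method observes it with its
#' own multiplicative lognormal noise; the hybrid method additionally
#' carries the multiplicative bias `bias`, which is recoverable by
#' [percentBias()] (bias 0.85 gives about -15 percent). All lognormal
#' perturbations are mean-one.
#'
#' @param true named numeric of true per-population values (any unit).
#' @param bias multiplicative bias of the hybrid method.
#' @param cvHybrid,cvManual per-method measurement coefficients of
#'   variation (0 gives exact proportionality and r = 1).
#' @param betweenCV between-sample biological coefficient of variation.
#' @param nSamples number of paired samples.
#' @param seed integer seed.
#' @return data.frame `sample_id, population, hybrid, manual`.
#' @export
generatePairedCounts <- function(true = c(Tcells = 1.2), bias = 1,
                                 cvHybrid = 0.05, cvManual = 0.05,
                                 betweenCV = 0.3, nSamples = 100, seed = 1L) {
  if (cvHybrid < 0 || cvManual < 0 || betweenCV < 0)
    preconditionError("coefficients of variation must be >= 0")
  ln <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    sdl <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, -sdl^2 / 2, sdl)
  }
  withSeed(seed, {
    do.call(rbind, lapply(names(true), function(pop) {
      t <- true[[pop]] * ln(nSamples, betweenCV)
      data.frame(sample_id = sprintf("s%04d", seq_len(nSamples)),
                 population = pop,
                 hybrid = bias * t * ln(nSamples, cvHybrid),
                 manual = t * ln(nSamples, cvManual),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Generate a technician variability design with known variance components
#'
#' Repeated control samples measured by several technicians: the value is a
#' fixed control effect plus a technician random effect (variance
#' `varInter`) plus replicate noise (variance `varIntra`), the design under
#' which [iccMixedModel()] recovers `ICC = varInter / (varInter +
#' varIntra)`.
#'
#' @param varInter,varIntra inter/intra-technician variance components.
#' @param nControls,nTechnicians,nReps design size (defaults: 8 controls x
#'   5 technicians x 4 replicates).
#' @param population population name stamped on the rows.
#' @param seed integer seed.
#' @return data.frame `control_id, technician_id, replicate, population,
#'   value` with attributes `varInter`, `varIntra`.
#' @export
generateTechnicianStudy <- function(varInter = 0.5, varIntra = 0.5,
                                    nControls = 8, nTechnicians = 5,
                                    nReps = 4, population = "Tcells",
                                    seed = 1L) {
  if (varInter < 0 || varIntra < 0)
    preconditionError("variance components must be >= 0")
  withSeed(seed, {
    controlMeans <- seq(20, 55, length.out = nControls)
    techEffect <- stats::rnorm(nTechnicians, 0, sqrt(varInter))
    grid <- expand.grid(control = seq_len(nControls),
                        technician = seq_len(nTechnicians),
                        replicate = seq_len(nReps))
    value <- controlMeans[grid$control] + techEffect[grid$technician] +
      stats::rnorm(nrow(grid), 0, sqrt(varIntra))
    structure(data.frame(control_id = sprintf("ctrl%02d", grid$control),
                         technician_id = sprintf("tech%02d", grid$technician),
                         replicate = grid$replicate, population = population,
                         value = value, stringsAsFactors = FALSE),
              varInter = varInter, varIntra = varIntra)
  })
}
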