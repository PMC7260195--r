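# Three-marker (CCR7, CD45RA, CD28) k-means caller for memory/effector
# T-cell subsets. The markers are z-scored, clustered with a pre-defined
# k = 4, each cluster is labelled +/- per marker by ranking cluster medians
# (top two medians are "+"), and the CCR7/CD45RA sign pair maps clusters to
# the four canonical subsets. A sample whose four sign pairs do not map
# one-to-one onto the subsets is flagged for manual gating.

TSUBSET_NAMES <- c("naive", "central_memory", "effector_memory", "effector")

# (CCR7, CD45RA) -> subset; CD28 expectations are a consistency check only.
SUBSET_SIGN_MAP <- c("++" = "naive", "+-" = "central_memory",
                     "--" = "effector_memory", "-+" = "effector")
CD28_EXPECTED <- c(naive = "+", effector = "-")

MIN_SUBSET_EVENTS <- 40L

#' Standardise markers for clustering
#'
#' Scales each column to sample mean 0 and standard deviation 1
#' (denominator n-1). Clustering runs on the scaled values; the +/-
#' labelling of clusters uses the unscaled marker values (the ranking is
#' unaffected by monotone scaling).
#'
#' @param x numeric matrix, events x markers.
#' @return Matrix of the same shape with standardised columns.
#' @export
scaleMarkers <- function(x) {
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    preconditionError(paste("zero-variance marker column(s):",
                            paste(colnames(x)[sds == 0], collapse = ", ")))
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

# k-means++ seeding (Arthur & Vassilvitskii): each new centre is drawn with
# probability proportional to squared distance from the nearest chosen one.
kmeansppInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    probs <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
    nd2 <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd2)
  }
  centers
}

#' Cluster scaled markers with k = 4
#'
#' Lloyd's k-means with k-means++ initialisation, `nRestarts` restarts under
#' a fixed seed, keeping the solution with the lowest within-cluster sum of
#' squares. A restart that produces an empty cluster is re-seeded.
#'
#' @param x scaled numeric matrix (see [scaleMarkers()]), n >= 40 rows.
#' @param seed integer seed; the full restart sequence is deterministic
#'   given the seed.
#' @param nRestarts number of k-means++ restarts.
#' @param maxIter Lloyd iteration cap per restart.
#' @return Integer vector of cluster ids in 1..4, with attribute
#'   `"tot.withinss"`.
#' @export
clusterK4 <- function(x, seed = 1L, nRestarts = 10L, maxIter = 300L) {
  if (nrow(x) < MIN_SUBSET_EVENTS)
    preconditionError(sprintf("k-means subset calling needs >= %d events, got %d",
                              MIN_SUBSET_EVENTS, nrow(x)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    km <- NULL
    for (attempt in 1:5) {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = kmeansppInit(x, 4),
                                       iter.max = maxIter, algorithm = "Lloyd")),
        error = function(e) NULL)  # empty cluster: re-seed this restart
      if (!is.null(km) && all(km$size > 0)) break
      km <- NULL
    }
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best))
    preconditionError("all k-means restarts degenerate; sample flagged")
  structure(as.integer(best$cluster), tot.withinss = best$tot.withinss)
}

#' Label clusters +/- per marker by median split
#'
#' For each marker independently, the two clusters with the highest median
#' marker value (over all events in the cluster, on the unscaled scale) are
#' labelled `"+"` and the other two `"-"`. Median ties rank the larger
#' cluster higher, then the lower cluster id, so the 2/2 split is always
#' deterministic.
#'
#' @param x unscaled marker matrix, events x 3 markers.
#' @param assignment integer cluster ids 1..4 (see [clusterK4()]).
#' @return 4 x 3 character matrix of `"+"`/`"-"`, rows = clusters, columns
#'   = markers.
#' @export
labelClusters <- function(x, assignment) {
  ids <- 1:4
  if (!all(ids %in% assignment))
    preconditionError("labelClusters requires four non-empty clusters")
  sizes <- tabulate(assignment, 4)
  signs <- matrix("-", 4, ncol(x), dimnames = list(NULL, colnames(x)))
  for (m in seq_len(ncol(x))) {
    med <- vapply(ids, function(k) stats::median(x[assignment == k, m]), 0)
    ord <- order(-med, -sizes, ids)
    signs[ord[1:2], m] <- "+"
  }
  signs
}

#' Map cluster sign triples to T-cell subsets
#'
#' Keyed on the (CCR7, CD45RA) sign pair: `(+,+)` naive, `(+,-)` central
#' memory, `(-,-)` effector memory, `(-,+)` effector (TEMRA). CD28 serves
#' as a secondary consistency check on the targeted phenotypes: naive is
#' expected CD28+ and effector CD28-. The sample is flagged for manual
#' gating when a cluster cannot be mapped to a targeted subset: the four
#' sign pairs are not a bijection onto the four subsets, or (by default) a
#' CD28 consistency check fails; set `flagOnCD28 = FALSE` to downgrade
#' CD28 mismatches to warnings.
#'
#' @param clusterSigns 4 x 3 `"+"`/`"-"` matrix from [labelClusters()],
#'   columns ordered (CCR7, CD45RA, CD28).
#' @param flagOnCD28 flag the sample (rather than only warn) when a CD28
#'   consistency check fails.
#' @return List with `labels` (character(4), subset per cluster), `flagged`
#'   and `notes`.
#' @export
mapSubsets <- function(clusterSigns, flagOnCD28 = TRUE) {
  pairs <- paste0(clusterSigns[, 1], clusterSigns[, 2])
  labels <- unname(SUBSET_SIGN_MAP[pairs])
  flagged <- anyDuplicated(pairs) > 0
  notes <- character()
  if (flagged)
    notes <- c(notes, "CCR7/CD45RA sign pairs do not map one-to-one onto the four subsets")
  for (k in 1:4) {
    exp28 <- CD28_EXPECTED[labels[k]]
    if (!is.na(labels[k]) && !is.na(exp28) && clusterSigns[k, 3] != exp28) {
      msg <- sprintf("cluster %d labelled %s but CD28 is '%s' (expected '%s')",
                     k, labels[k], clusterSigns[k, 3], exp28)
      notes <- c(notes, msg)
      if (flagOnCD28) flagged <- TRUE else warning(msg, call. = FALSE)
    }
  }
  list(labels = labels, flagged = flagged, notes = notes)
}

#' Call the eight memory/effector T-cell subset populations
#'
#' Runs the full three-marker pipeline on the pooled CD4+ helper and CD8+
#' cytotoxic T cells of one sample: scale, cluster (k = 4), label clusters
#' +/- per marker, map to subsets, then split the four labelled subsets by
#' their original parent to obtain eight populations. A flagged sample
#' still returns counts; the flag routes it to manual gating.
#'
#' @param x numeric matrix of events x 3 markers, column order
#'   (CCR7, CD45RA, CD28).
#' @param parent character/factor of per-event parent labels (e.g. "CD4",
#'   "CD8").
#' @param seed integer seed for the clustering restarts.
#' @param parents the parent labels expected in the output (defaults to the
#'   distinct values of `parent`); parents with no events get zero counts.
#' @param flagOnCD28 see [mapSubsets()].
#' @param perParent cluster each parent separately instead of pooling
#'   (optional mode; the default pools, matching joint clustering of a
#'   sample's helper and cytotoxic T cells).
#' @return A [SubsetCall-class].
#' @examples
#' sim <- generateTcellSample(n = 2000, separation = 6, seed = 1)
#' call <- callSubsets(sim$markers, sim$parent, seed = 1)
#' subsetCounts(call)
#' @export
callSubsets <- function(x, parent, seed = 1L, parents = NULL,
                        flagOnCD28 = TRUE, perParent = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != 3) preconditionError("subset calling requires exactly 3 markers")
  parent <- as.character(parent)
  if (length(parent) != nrow(x))
    preconditionError("parent labels must match the number of events")
  parents <- parents %||% sort(unique(parent))

  if (perParent) {
    calls <- lapply(parents, function(p) {
      sel <- parent == p
      callSubsets(x[sel, , drop = FALSE], parent[sel], seed = seed,
                  parents = p, flagOnCD28 = flagOnCD28)
    })
    counts <- do.call(rbind, lapply(calls, subsetCounts))
    assignment <- integer(nrow(x))
    for (i in seq_along(parents))
      assignment[parent == parents[i]] <- calls[[i]]@assignment
    return(new("SubsetCall", assignment = assignment,
               clusterSigns = calls[[1]]@clusterSigns,
               subsetLabels = calls[[1]]@subsetLabels,
               flagged = any(vapply(calls, isFlagged, TRUE)),
               counts = counts, seed = as.integer(seed),
               notes = unlist(lapply(calls, function(cl) cl@notes))))
  }

  xs <- scaleMarkers(x)
  assignment <- clusterK4(xs, seed = seed)
  signs <- labelClusters(x, assignment)
  mapped <- mapSubsets(signs, flagOnCD28 = flagOnCD28)

  counts <- do.call(rbind, lapply(parents, function(p) {
    np <- sum(parent == p)
    cnt <- vapply(TSUBSET_NAMES, function(s) {
      sum(parent == p & mapped$labels[assignment] == s)
    }, 0L)
    data.frame(parent = p, subset = TSUBSET_NAMES, count = as.integer(cnt),
               pct_of_parent = if (np > 0) 100 * cnt / np else 0,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  new("SubsetCall", assignment = assignment, clusterSigns = signs,
      subsetLabels = mapped$labels, flagged = mapped$flagged,
      counts = counts, seed = as.integer(seed), notes = mapped$notes)
}
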