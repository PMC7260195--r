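test_that("marker scaling gives exact z-scores and is idempotent", {
  x <- cbind(CCR7 = c(1, 2, 3), CD45RA = c(2, 4, 6), CD28 = c(0, 1, 2))
  s <- scaleMarkers(x)
  expect_equal(s[, "CCR7"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(scaleMarkers(s), s, tolerance = 1e-12, ignore_attr = TRUE)
  x[, 2] <- 5
  expect_error(scaleMarkers(x), "zero-variance",
               class = "cytoPreconditionError")
})

test_that("k-means with k-means++ restarts recovers four separated clusters", {
  withr::with_seed(31, {
    centers <- rbind(c(-3, -3, 0), c(3, -3, 0), c(-3, 3, 0), c(3, 3, 0))
    truth <- sample(1:4, 2000, replace = TRUE)
    x <- centers[truth, ] + matrix(rnorm(6000, 0, 0.3), 2000, 3)
  })
  a <- clusterK4(x, seed = 7)
  expect_gte(adjustedRand(a, truth), 0.99)
  expect_identical(a, clusterK4(x, seed = 7))  # determinism under fixed seed
  expect_error(clusterK4(x[1:20, ], seed = 1),
               class = "cytoPreconditionError")
})

test_that("median split labels exactly two clusters '+' per marker", {
  x <- cbind(CCR7 = rep(c(5, 4, 1, 0.5), each = 10),
             CD45RA = rep(c(1, 5, 1, 5), each = 10),
             CD28 = rep(c(5, 5, 1, 1), each = 10))
  a <- rep(1:4, each = 10)
  signs <- labelClusters(x, a)
  expect_identical(signs[, "CCR7"], c("+", "+", "-", "-"))
  expect_true(all(colSums(signs == "+") == 2))
})

test_that("median ties resolve by cluster size then id, still two '+' two '-'", {
  x <- cbind(CCR7 = rep(1, 100), CD45RA = rep(1, 100), CD28 = rep(1, 100))
  a <- rep(1:4, times = c(40, 10, 30, 20))
  signs <- labelClusters(x, a)
  expect_true(all(colSums(signs == "+") == 2))
  # sizes 40 and 30 (clusters 1 and 3) outrank the tied medians
  expect_identical(signs[, "CCR7"], c("+", "-", "+", "-"))
  # tied medians with tied sizes fall back to cluster id
  a2 <- rep(1:4, each = 25)
  expect_identical(labelClusters(x, a2)[, "CCR7"], c("+", "+", "-", "-"))
})

test_that("sign triples map to the canonical subsets; failures flag", {
  canon <- rbind(c("+", "+", "+"), c("+", "-", "+"),
                 c("-", "-", "-"), c("-", "+", "-"))
  m <- mapSubsets(canon)
  expect_identical(m$labels, c("naive", "central_memory",
                               "effector_memory", "effector"))
  expect_false(m$flagged)

  dup <- canon; dup[2, ] <- c("+", "+", "-")
  expect_true(mapSubsets(dup)$flagged)

  # effector cluster showing CD28+ fails the consistency check
  cd28 <- canon; cd28[4, 3] <- "+"; cd28[3, 3] <- "-"
  expect_true(mapSubsets(cd28)$flagged)
  expect_warning(m2 <- mapSubsets(cd28, flagOnCD28 = FALSE), "CD28")
  expect_false(m2$flagged)
})

test_that("callSubsets recovers known subset fractions and conserves counts", {
  fr <- c(naive = 0.40, central_memory = 0.25, effector_memory = 0.25,
          effector = 0.10)
  sim <- generateTcellSample(fractions = fr, n = 20000, separation = 6,
                             seed = 41)
  call <- callSubsets(sim$markers, sim$parent, seed = 41)
  expect_false(isFlagged(call))
  cnt <- subsetCounts(call)
  for (p in c("CD4", "CD8")) {
    np <- sum(sim$parent == p)
    sub <- cnt[cnt$parent == p, ]
    expect_equal(sum(sub$count), np)  # exact partition of the parent
    truthFrac <- table(factor(sim$subset[sim$parent == p],
                              levels = sub$subset)) / np
    expect_lt(max(abs(sub$pct_of_parent / 100 - as.numeric(truthFrac))), 0.01)
  }
})

test_that("single-parent input yields zero counts for the absent parent", {
  sim <- generateTcellSample(n = 4000, separation = 6, seed = 42)
  sel <- sim$parent == "CD4"
  call <- callSubsets(sim$markers[sel, ], sim$parent[sel], seed = 1,
                      parents = c("CD4", "CD8"))
  cnt <- subsetCounts(call)
  expect_true(all(cnt$count[cnt$parent == "CD8"] == 0))
  expect_equal(sum(cnt$count[cnt$parent == "CD4"]), sum(sel))
})

test_that("subset counts are invariant to the clustering seed on easy data", {
  sim <- generateTcellSample(n = 6000, separation = 6, seed = 43)
  c1 <- callSubsets(sim$markers, sim$parent, seed = 1)
  c2 <- callSubsets(sim$markers, sim$parent, seed = 99)
  expect_identical(subsetCounts(c1), subsetCounts(c2))
})

test_that("invalid subset-caller inputs raise precondition errors", {
  sim <- generateTcellSample(n = 1000, separation = 6, seed = 44)
  expect_error(callSubsets(sim$markers[, 1:2], sim$parent[1:1000]),
               class = "cytoPreconditionError")
  expect_error(callSubsets(sim$markers, sim$parent[1:10]),
               class = "cytoPreconditionError")
})
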