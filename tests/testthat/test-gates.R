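test_that("density cut falls in the valley of an equal two-component mixture", {
  x <- withr::with_seed(11, c(rnorm(5000, 0, 0.2), rnorm(5000, 4, 0.2)))
  cut <- densityCut1d(x, "+")
  expect_gt(cut, 1.5)
  expect_lt(cut, 2.5)
})

test_that("single-peak cut lands on the shoulder found by a brute-force scan", {
  x <- withr::with_seed(12, rnorm(5000))
  cut <- densityCut1d(x, "+", minPeakHeight = 0.05, expectedPeaks = 1)
  expect_gt(cut, 0)
  expect_equal(as.numeric(cut), shoulderScanOracle(x, 0.05), tolerance = 1e-8)
})

test_that("density gates are deterministic and respect the event floor", {
  x <- withr::with_seed(13, c(rnorm(500, 0, 0.3), rnorm(500, 3, 0.3)))
  expect_identical(densityCut1d(x, "+"), densityCut1d(x, "+"))
  expect_error(densityCut1d(rnorm(10), "+"), "low cell count|events",
               class = "cytoGateError")
  err <- tryCatch(densityCut1d(rnorm(10), "+"), cytoGateError = identity)
  expect_equal(err$tag, "low_cell_count")
})

test_that("quadrant gate recovers four well-separated blobs and partitions exactly", {
  n <- 2000
  blob <- withr::with_seed(14, {
    cx <- rep(c(-4, 4, -4, 4), each = n)
    cy <- rep(c(-4, -4, 4, 4), each = n)
    cbind(x = cx + rnorm(4 * n, 0, 0.5), y = cy + rnorm(4 * n, 0, 0.5))
  })
  qg <- quadrantGate(blob[, "x"], blob[, "y"])
  counts <- vapply(qg$quadrants, sum, 0)
  expect_equal(sum(counts), 4 * n)  # exact partition, no dead zone
  expect_equal(Reduce(`+`, lapply(qg$quadrants, as.integer)),
               rep(1L, 4 * n))     # disjoint cover
  truthQ <- paste0(ifelse(blob[, "x"] > 0, "+", "-"),
                   ifelse(blob[, "y"] > 0, "+", "-"))
  for (q in names(qg$quadrants))
    expect_gte(sum(qg$quadrants[[q]] & truthQ == q) / sum(truthQ == q), 0.99)
  # sign semantics: "+-" is the x-positive / y-negative quadrant
  expect_true(all(blob[qg$quadrants[["+-"]], "x"] > qg$cx))
  expect_true(all(blob[qg$quadrants[["+-"]], "y"] <= qg$cy))
})

test_that("singlet gate keeps singlets and rejects sub-additive doublets", {
  withr::with_seed(15, {
    a <- runif(5000, 3e4, 1.5e5)
    h <- 0.98 * a + rnorm(5000, 0, 1500)
    keep <- singletGate(a, h)
    expect_gte(mean(keep), 0.99)
    # 10% doublets: FSC-H about 0.59 of FSC-A, far below the band
    nd <- 500
    a2 <- c(a, runif(nd, 6e4, 3e5))
    h2 <- c(h, 0.6 * 0.98 * a2[5001:5500] + rnorm(nd, 0, 1500))
    keep2 <- singletGate(a2, h2)
    expect_lte(mean(keep2[5001:5500]), 0.01)
    expect_gte(mean(keep2[1:5000]), 0.99)
  })
  expect_error(singletGate(1:5, 1:5), class = "cytoGateError")
  expect_error(singletGate(rep(0, 100), rep(0, 100)), "degenerate",
               class = "cytoGateError")
})
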