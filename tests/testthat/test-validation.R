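test_that("Pearson r is exact on proportional data and its CI matches cor.test", {
  pairs <- data.frame(hybrid = 2 * (1:20), manual = 1:20)
  ci <- pearsonCI(pairs)
  expect_equal(unname(ci["r"]), 1)
  withr::with_seed(51, {
    pairs2 <- data.frame(hybrid = rnorm(50) + (1:50) / 10, manual = rnorm(50))
  })
  ci2 <- pearsonCI(pairs2)
  ct <- stats::cor.test(pairs2$hybrid, pairs2$manual)
  expect_equal(unname(ci2["r"]), unname(ct$estimate))
  expect_equal(unname(ci2[c("lo", "hi")]), as.numeric(ct$conf.int),
               tolerance = 1e-8)
})

test_that("independent data give near-zero correlation and preconditions hold", {
  withr::with_seed(52, {
    pairs <- data.frame(hybrid = rnorm(1000), manual = rnorm(1000))
  })
  expect_lt(abs(pearsonCI(pairs)["r"]), 0.1)
  expect_error(pearsonCI(data.frame(hybrid = 1:3, manual = 3:1)),
               class = "cytoPreconditionError")
  expect_error(pearsonCI(data.frame(hybrid = rep(1, 10), manual = 1:10)),
               "constant", class = "cytoPreconditionError")
})

test_that("percent bias matches its definition and is scale-equivariant", {
  m <- c(1, 2, 3, 4, 5)
  expect_equal(unname(percentBias(data.frame(hybrid = m, manual = m),
                                  nBoot = 50)["bias"]), 0)
  expect_equal(unname(percentBias(data.frame(hybrid = 1.1 * m, manual = m),
                                  nBoot = 50)["bias"]), 10, tolerance = 1e-9)
  withr::with_seed(53, {
    pairs <- data.frame(hybrid = rlnorm(40), manual = rlnorm(40))
  })
  b1 <- percentBias(pairs, nBoot = 100, seed = 9)
  pairs2 <- pairs * 7.3
  b2 <- percentBias(pairs2, nBoot = 100, seed = 9)
  expect_equal(b1, b2, tolerance = 1e-9)
  expect_error(percentBias(data.frame(hybrid = 1:3, manual = rep(0, 3))),
               class = "cytoPreconditionError")
  # mean-of-ratios alternative
  mr <- percentBias(data.frame(hybrid = c(2, 2), manual = c(1, 4)),
                    method = "mean_of_ratios", nBoot = 50)
  expect_equal(unname(mr["bias"]), 100 * mean(c(2 / 1, 2 / 4) - 1))
})

test_that("signed and absolute differences follow their definitions", {
  expect_equal(absoluteDifference(data.frame(hybrid = c(1, 2), manual = c(2, 1))),
               c(mean_diff = 0, mean_abs_diff = 1))
  expect_equal(absoluteDifference(data.frame(hybrid = c(3), manual = c(1))),
               c(mean_diff = 2, mean_abs_diff = 2))
})

test_that("F-measure reproduces the confusion-matrix formula", {
  # TP=2, FP=1, FN=1 -> 2*2/(2*2+1+1) = 2/3
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(fMeasure(a, b), 2 / 3)
  expect_equal(round(fMeasure(a, b), 4), 0.6667)
  expect_equal(fMeasure(b, b), 1)
  expect_equal(fMeasure(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(fMeasure(logical(5), logical(5)), 1)  # degenerate convention
  expect_error(fMeasure(logical(3), logical(4)), class = "cytoPreconditionError")
})

test_that("F-measure equals brute force on many random mask pairs", {
  withr::with_seed(54, {
    for (i in 1:300) {
      n <- sample(5:60, 1)
      a <- runif(n) < runif(1)
      b <- runif(n) < runif(1)
      expect_identical(fMeasure(a, b), bruteForceF(a, b))
    }
  })
})

test_that("3-SD outlier screening follows the either-method single-pass rule", {
  withr::with_seed(55, {
    base <- rnorm(99, 0, 1)
    pairs <- data.frame(hybrid = c(base, 100), manual = c(base, 0))
  })
  flt <- removeOutliers(pairs)
  expect_equal(flt$nRemoved, 1)       # hybrid-only outlier still removed
  expect_equal(nrow(flt$pairs), 99)
  same <- data.frame(hybrid = rep(2, 20), manual = rep(3, 20))
  expect_equal(removeOutliers(same)$nRemoved, 0)
  # no outliers: r unchanged exactly
  withr::with_seed(56, {
    p2 <- data.frame(hybrid = rnorm(30), manual = rnorm(30))
  })
  if (removeOutliers(p2)$nRemoved == 0)
    expect_identical(pearsonCI(removeOutliers(p2)$pairs)["r"], pearsonCI(p2)["r"])
  expect_error(removeOutliers(pairs[1:5, ]), class = "cytoPreconditionError")
})

test_that("the optimization gate is strict at 0.75", {
  expect_true(optimizationGate(0.76))
  expect_false(optimizationGate(0.75))
  expect_false(optimizationGate(-0.2))
  expect_error(optimizationGate(NaN), class = "cytoPreconditionError")
})

test_that("the comparison report covers every population with reason codes", {
  withr::with_seed(57, {
    good <- generatePairedCounts(true = c(Tcells = 1.2), bias = 0.9,
                                 nSamples = 60, seed = 57)
    flat <- data.frame(sample_id = sprintf("s%02d", 1:12),
                       population = "deadpop", hybrid = rnorm(12),
                       manual = rep(2, 12))
  })
  rep <- buildReport(rbind(good, flat), seed = 3)
  expect_s3_class(rep, "ComparisonReport")
  expect_setequal(rep$population, c("Tcells", "deadpop"))
  expect_match(rep$reason[rep$population == "deadpop"], "undefined_correlation")
  expect_false(is.na(rep$r[rep$population == "Tcells"]))
  expect_false(is.na(rep$r_after_outlier_removal[rep$population == "Tcells"]))

  csv <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".md")
  writeReport(rep, csvPath = csv, mdPath = md, seed = 3)
  back <- utils::read.csv(csv, comment.char = "#")
  expect_equal(back$r[back$population == "Tcells"],
               rep$r[rep$population == "Tcells"], tolerance = 1e-12)
  expect_true(any(grepl("percent bias", readLines(md))))
})
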