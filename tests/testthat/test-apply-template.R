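bimodalMatrix <- function(n = 4000, seed = 21) {
  withr::with_seed(seed, {
    m <- cbind(ch1 = c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 4, 0.3)),
               ch2 = c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 4, 0.3))[sample(n)])
    EventMatrix(m, sampleId = "bimodal")
  })
}

inlineTemplate <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("alias,parent,dims,method,sign,args", lines), path)
  parseGatingTemplate(path)
}

test_that("a mindensity gate on an equal mixture captures about half the events", {
  em <- bimodalMatrix()
  res <- applyTemplate(em, inlineTemplate("A,root,ch1,mindensity,+,"))
  expect_lt(abs(populations(res)$A@count - nEvents(em) / 2),
            0.02 * nEvents(em))
})

test_that("nested memberships are subsets and pct_of_total chains multiply", {
  em <- bimodalMatrix()
  res <- applyTemplate(em, inlineTemplate(c(
    "A,root,ch1,mindensity,+,",
    "B,A,ch2,mindensity,+,")))
  expect_true(all(membership(res, "B") <= membership(res, "A")))
  pA <- populations(res)$A
  pB <- populations(res)$B
  expect_equal(pB@pctOfTotal,
               pA@pctOfParent / 100 * pB@pctOfParent / 100 * 100,
               tolerance = 1e-9)
})

test_that("absolute counts follow percent-of-total times WBC", {
  withr::with_seed(22, {
    m <- cbind(ch1 = c(rep(0, 90), rep(10, 10)) + rnorm(100, 0, 0.01),
               ch2 = rnorm(100))
  })
  em <- EventMatrix(m, sampleId = "wbc")
  res <- applyTemplate(em, inlineTemplate(
    'A,root,ch1:ch2,rect,,"bounds=[5,15,-10,10]"'), wbc = 6.0)
  p <- populations(res)$A
  expect_equal(p@pctOfTotal, 10)
  expect_equal(p@absCount, 0.6)
})

test_that("four quadrant children partition their parent exactly", {
  withr::with_seed(23, {
    n <- 1200
    m <- cbind(ch1 = rep(c(-4, 4), each = 2 * n) + rnorm(4 * n, 0, 0.5),
               ch2 = rep(c(-4, 4, -4, 4), each = n) + rnorm(4 * n, 0, 0.5))
  })
  em <- EventMatrix(m, sampleId = "quad")
  res <- applyTemplate(em, inlineTemplate(c(
    "Q1,root,ch1:ch2,quadrant,++,", "Q2,root,ch1:ch2,quadrant,+-,",
    "Q3,root,ch1:ch2,quadrant,-+,", "Q4,root,ch1:ch2,quadrant,--,")))
  counts <- vapply(populations(res), function(p) p@count, 0L)
  expect_equal(sum(counts), nEvents(em))
})

test_that("gate failures tag the subtree without aborting the sample", {
  em <- bimodalMatrix(n = 1000)
  res <- applyTemplate(em, inlineTemplate(c(
    'empty,root,ch1:ch2,rect,,"bounds=[100,200,100,200]"',
    "child,empty,ch1,mindensity,+,",
    "grandchild,child,ch2,mindensity,+,",
    "ok,root,ch1,mindensity,+,")))
  expect_equal(populations(res)$empty@count, 0L)
  child <- populations(res)$child
  expect_equal(child@count, 0L)
  expect_true("low_cell_count" %in% child@flags)
  expect_true("low_cell_count" %in% populations(res)$grandchild@flags)
  expect_gt(populations(res)$ok@count, 0)  # sibling unaffected
})

test_that("boolean gates combine earlier aliases and bad references are flagged", {
  em <- bimodalMatrix()
  res <- applyTemplate(em, inlineTemplate(c(
    "A,root,ch1,mindensity,+,",
    "B,root,ch2,mindensity,+,",
    "AnotB,root,,boolean,,expr=A&!B")))
  expect_identical(membership(res, "AnotB"),
                   membership(res, "A") & !membership(res, "B"))
  res2 <- applyTemplate(em, inlineTemplate(
    "bad,root,,boolean,,expr=A&!missing"))
  expect_false(is.na(gateNodes(res2)$bad@error))
  expect_true("needs_manual_refinement" %in% populations(res2)$bad@flags)
})

test_that("template application is deterministic", {
  sim <- generateSample(smallPanelSpec(), seed = 5)
  t <- hipTemplate()
  r1 <- applyTemplate(sim$events, t)
  r2 <- applyTemplate(sim$events, t)
  expect_identical(countsTable(r1), countsTable(r2))
  expect_identical(lapply(gateNodes(r1), function(n) n@geometry),
                   lapply(gateNodes(r2), function(n) n@geometry))
})

test_that("gate JSON export round-trips geometry and reports errors", {
  em <- bimodalMatrix(n = 1000)
  res <- applyTemplate(em, inlineTemplate(c(
    "A,root,ch1,mindensity,+,",
    'empty,root,ch1:ch2,rect,,"bounds=[100,200,100,200]"',
    "childfail,empty,ch1,mindensity,+,")))
  path <- withr::local_tempfile(fileext = ".json")
  exportGatesJSON(res, path)
  doc <- loadGatesJSON(path)
  expect_equal(doc$sample_id, "bimodal")
  byAlias <- setNames(doc$gates, vapply(doc$gates, `[[`, "", "alias"))
  expect_equal(byAlias$A$geometry$cut, gateNodes(res)$A@geometry$cut)
  expect_null(byAlias$childfail$geometry)
  expect_type(byAlias$childfail$error, "character")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeCountsCSV(res, csv, seed = 1)
  tab <- utils::read.csv(csv, comment.char = "#")
  expect_identical(names(tab), c("sample_id", "alias", "count",
                                 "pct_of_parent", "pct_of_total",
                                 "abs_count", "flags"))
})
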