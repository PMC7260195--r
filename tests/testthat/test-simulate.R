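test_that("generated population fractions match the spec within sampling error", {
  spec <- defaultPanelSpec(nEvents = 50000)
  sim <- generateSample(spec, seed = 61)
  clean <- !sim$truth$isDoublet & !sim$truth$isDead
  lymph <- clean & grepl("/lymphocytes", sim$truth$path)
  tc <- lymph & grepl("/Tcells", sim$truth$path)
  expect_lt(abs(sum(tc) / sum(lymph) - 0.55), 0.01)
})

test_that("generation is deterministic under a fixed seed", {
  s1 <- generateSample(smallPanelSpec(2000), seed = 62)
  s2 <- generateSample(smallPanelSpec(2000), seed = 62)
  expect_identical(eventData(s1$events), eventData(s2$events))
  expect_identical(s1$truth, s2$truth)
  d1 <- generateTechnicianStudy(0.5, 0.5, seed = 62)
  d2 <- generateTechnicianStudy(0.5, 0.5, seed = 62)
  expect_identical(d1$value, d2$value)
})

test_that("without doublets the singlet gate retains nearly everything", {
  spec <- defaultPanelSpec(nEvents = 10000, doubletFraction = 0)
  sim <- generateSample(spec, seed = 63)
  d <- eventData(sim$events)
  keep <- singletGate(d[, "FSC-A"], d[, "FSC-H"])
  expect_gte(mean(keep), 0.995)
})

test_that("doublets are excluded by the singlet gate at the generated rate", {
  sim <- generateSample(defaultPanelSpec(nEvents = 20000), seed = 64)
  d <- eventData(sim$events)
  keep <- singletGate(d[, "FSC-A"], d[, "FSC-H"])
  expect_lte(mean(keep[sim$truth$isDoublet]), 0.05)
  expect_gte(mean(keep[!sim$truth$isDoublet]), 0.99)
})

test_that("invalid panel specs and subset fractions are rejected", {
  spec <- defaultPanelSpec(nEvents = 1000)
  spec$populations[[2]]$fraction <- 0.95  # with debris 0.08 the root overflows
  expect_error(generateSample(spec, seed = 1), "sum",
               class = "cytoPreconditionError")
  expect_error(generateTcellSample(fractions = c(naive = 0.5,
                                                 central_memory = 0.5,
                                                 effector_memory = 0.2,
                                                 effector = 0.2)),
               class = "cytoPreconditionError")
})

test_that("paired-count generation encodes an exactly recoverable bias", {
  p <- generatePairedCounts(true = c(Tcells = 1.5), bias = 0.85,
                            cvHybrid = 0, cvManual = 0, nSamples = 50,
                            seed = 65)
  expect_equal(unname(pearsonCI(p)["r"]), 1)  # exact proportionality
  expect_equal(unname(percentBias(p, nBoot = 50)["bias"]), -15,
               tolerance = 1e-9)
})

test_that("t-cell sample truth labels line up with the emitted components", {
  sim <- generateTcellSample(n = 3000, separation = 8, seed = 66)
  # at extreme separation, each event's nearest sign-table corner is its label
  centers <- cytoHybrid:::SUBSET_SIGNS * 4
  nearest <- apply(sim$markers, 1, function(v) {
    rownames(centers)[which.min(colSums((t(centers) - v)^2))]
  })
  expect_gte(mean(nearest == sim$subset), 0.999)
})
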