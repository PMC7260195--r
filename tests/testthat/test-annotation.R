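test_that("annotation store is latest-wins and validates the vocabulary", {
  st <- annotationStore()
  st <- recordAnnotation(st, "s1", "Tcell", "good", "ana")
  st <- recordAnnotation(st, "s1", "Tcell", "bad", "ana")
  eff <- effectiveTags(st)
  expect_equal(nrow(eff), 1)
  expect_equal(eff$tag, "bad")
  expect_equal(nrow(annotationRecords(st)), 2)  # history kept
  expect_error(recordAnnotation(st, "s1", "Tcell", "maybe"),
               "good.*bad.*needs_manual_refinement.*low_cell_count",
               class = "cytoPreconditionError")
})

test_that("store persistence round-trips the effective view exactly", {
  st <- annotationStore()
  st <- recordAnnotation(st, "s1", "Tcell", "good")
  st <- recordAnnotation(st, "s2", "Tcell", "needs_manual_refinement")
  st <- recordAnnotation(st, "s1", "Tcell", "low_cell_count")
  path <- withr::local_tempfile(fileext = ".csv")
  writeAnnotations(st, path)
  expect_identical(effectiveTags(readAnnotations(path)), effectiveTags(st))
})

test_that("tag summary reports the global manually-tagged fraction exactly", {
  samples <- sprintf("s%03d", 1:100)
  st <- annotationStore()
  for (s in samples) st <- recordAnnotation(st, s, "Tcell", "good")
  for (s in samples[1:11])
    st <- recordAnnotation(st, s, "Bcell", "needs_manual_refinement")
  sm <- summarizeTags(st, samples = samples)
  expect_equal(sm$globalFraction, 0.11)
  expect_equal(sm$perGate$fraction[sm$perGate$gate_alias == "Bcell"], 0.11)
  expect_setequal(sm$flagged$sample_id, samples[1:11])
  # the hand-off list only contains annotated pairs
  key <- paste(annotationRecords(st)$sample_id, annotationRecords(st)$gate_alias)
  expect_true(all(paste(sm$flagged$sample_id, sm$flagged$gate_alias) %in% key))
})

test_that("unreviewed gates report zero and all-good batches route nothing", {
  st <- recordAnnotation(annotationStore(), "s1", "Tcell", "good")
  sm <- summarizeTags(st, samples = "s1", aliases = c("Tcell", "NK"))
  expect_equal(sm$globalFraction, 0)
  expect_equal(nrow(sm$flagged), 0)
  nk <- sm$perGate[sm$perGate$gate_alias == "NK", ]
  expect_false(nk$reviewed)
  expect_equal(nk$fraction, 0)
})

test_that("plot pre-generation writes one deterministic file per gate", {
  sims <- lapply(1:2, function(i) generateSample(smallPanelSpec(3000), seed = i))
  tpl <- parseGatingTemplate(local({
    p <- tempfile(fileext = ".csv")
    writeLines(c("alias,parent,dims,method,sign,args",
                 "singlets,root,FSC-A:FSC-H,singlet,,",
                 'lymph,singlets,FSC-A:SSC-A,rect,,"bounds=[55000,95000,5000,55000]"',
                 "T,lymph,CD3,mindensity,+,",
                 'fail,root,CD3:CD19,rect,,"bounds=[100,200,100,200]"',
                 "failchild,fail,CD3,mindensity,+,"), p)
    p
  }))
  results <- lapply(sims, function(s) applyTemplate(s$events, tpl))
  outdir <- withr::local_tempdir()
  files <- pregeneratePlots(results, lapply(sims, `[[`, "events"), outdir)
  expect_length(files, 2 * 5)
  expect_true(file.exists(file.path(outdir, "sim001__T.png")))
  expect_true(file.exists(file.path(outdir, "sim002__failchild.png")))
  # idempotent: same file set on re-run
  files2 <- pregeneratePlots(results, lapply(sims, `[[`, "events"), outdir)
  expect_identical(sort(files), sort(files2))
})
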