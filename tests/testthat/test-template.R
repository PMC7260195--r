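writeTemplate <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("alias,parent,dims,method,sign,args", lines), path)
  path
}

test_that("a valid three-row template parses in order with resolved parents", {
  t <- parseGatingTemplate(writeTemplate(c(
    "lymph,root,CD3,mindensity,+,",
    'Tcell,lymph,CD3:CD19,quadrant,+-,"gate_range=[0,3];expected_peaks=2"',
    "Tsub,Tcell,CD4,mindensity,+,")))
  expect_s4_class(t, "GatingTemplate")
  expect_length(t, 3)
  expect_identical(t@rows[[2]]$parent, "lymph")
  expect_identical(t@rows[[2]]$sign, c("+", "-"))
})

test_that("typed args parse to numeric vectors, scalars and name lists", {
  t <- parseGatingTemplate(writeTemplate(
    'A,root,CD3,mindensity,+,"gate_range=[0,3];expected_peaks=2;bandwidth=auto;markers=CCR7:CD45RA:CD28"'))
  args <- t@rows[[1]]$args
  expect_identical(args$gate_range, c(0, 3))
  expect_identical(args$expected_peaks, 2)
  expect_identical(args$bandwidth, "auto")
  expect_identical(args$markers, c("CCR7", "CD45RA", "CD28"))
})

test_that("template structural errors name the offending row", {
  expect_error(parseGatingTemplate(writeTemplate(c(
    "A,root,CD3,mindensity,+,", "B,C,CD4,mindensity,+,"))),
    "orphan parent.*row 2", class = "cytoTemplateError")
  expect_error(parseGatingTemplate(writeTemplate(c(
    "A,root,CD3,mindensity,+,", "A,root,CD4,mindensity,+,"))),
    "duplicate alias", class = "cytoTemplateError")
  expect_error(parseGatingTemplate(writeTemplate(
    "A,root,CD3,magic,+,")), "unknown method", class = "cytoTemplateError")
  # forward references (cycles) are orphans at parse time
  expect_error(parseGatingTemplate(writeTemplate(c(
    "A,B,CD3,mindensity,+,", "B,A,CD4,mindensity,+,"))),
    "orphan parent", class = "cytoTemplateError")
})

test_that("method arity and sign requirements are enforced", {
  expect_error(parseGatingTemplate(writeTemplate(
    "A,root,CD3:CD19,mindensity,+,")), "one dim", class = "cytoTemplateError")
  expect_error(parseGatingTemplate(writeTemplate(
    "A,root,CD3:CD19,quadrant,+,")), "sign", class = "cytoTemplateError")
})
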