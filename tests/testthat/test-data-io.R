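test_that("delimited matrices parse with and without channel selection", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "0,0", "1,1"), path)
  mat <- readEvents(path, format = "delimited")
  expect_identical(dim(mat), c(2L, 2L))
  expect_identical(colnames(mat), c("x", "y"))

  sub <- readEvents(path, channels = "y")
  expect_identical(dim(sub), c(2L, 1L))
  expect_equal(unname(sub[, 1]), c(0, 1))

  expect_error(readEvents(path, channels = "z"), "unknown channel")

  tabPath <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a\tb", "1.5\t2.5", "3\t4"), tabPath)
  tsv <- readEvents(tabPath)
  expect_equal(unname(tsv[2, ]), c(3, 4))

  headerless <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2", "3,4"), headerless)
  hm <- readEvents(headerless)
  expect_identical(dim(hm), c(2L, 2L))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,apple"), bad)
  expect_error(readEvents(bad), "non-numeric")
})

test_that("FCS fixtures round-trip through the reader", {
  set.seed(11)
  mat <- matrix(rnorm(300), ncol = 3,
                dimnames = list(NULL, c("FSC-A", "SSC-A", "FL1-A")))
  path <- withr::local_tempfile(fileext = ".fcs")
  writeMiniFCS(path, mat)

  got <- readEvents(path)          # .fcs extension autodetected
  expect_identical(dim(got), c(100L, 3L))
  expect_identical(colnames(got), colnames(mat))
  expect_equal(got, mat, tolerance = 1e-6)  # float32 storage

  one <- readEvents(path, format = "fcs", channels = "FL1-A")
  expect_equal(unname(one[, 1]), unname(mat[, 3]), tolerance = 1e-6)

  expect_error(readEvents(path, channels = "nope"), "unknown channel")
})

test_that("label files round-trip and reject empty input", {
  path <- withr::local_tempfile()
  writeLabels(path, c(1L, 1L, 2L))
  expect_identical(readLines(path), c("1", "1", "2"))
  expect_identical(readLabels(path), c(1L, 1L, 2L))
  expect_error(writeLabels(path, integer()), "at least one")
})

test_that("the pipeline is deterministic and labels every event once", {
  dat <- twoGaussians(nPer = 300, gap = 15, seed = 5)
  cfg <- runConfig(sigma = 0.7, m = 120L, seed = 99L)
  res1 <- runPipeline(dat$events, cfg)
  res2 <- runPipeline(dat$events, cfg)
  expect_identical(eventLabels(res1), eventLabels(res2))

  labels <- eventLabels(res1)
  expect_length(labels, nrow(dat$events))
  expect_setequal(unique(labels), seq_len(componentCount(res1)))
})

test_that("well-separated Gaussians resolve into two components matching truth", {
  dat <- twoGaussians(nPer = 2000, gap = 20, seed = 42)
  res <- runPipeline(dat$events, runConfig(sigma = 0.7, m = 200L, seed = 3L))
  expect_identical(componentCount(res), 2L)
  expect_equal(fMeasure(dat$truth, eventLabels(res)), 1)
})

test_that("a single event yields one component labelled 1", {
  res <- runPipeline(matrix(c(1, 2), nrow = 1), runConfig(sigma = 1, seed = 1))
  expect_identical(eventLabels(res), 1L)
  expect_identical(componentCount(res), 1L)
})

test_that("diagnostics serialize to JSON with the audit fields", {
  dat <- twoGaussians(nPer = 200, gap = 15, seed = 8)
  res <- runPipeline(dat$events, runConfig(sigma = 0.7, m = 80L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".json")
  writeDiagnostics(res, path)
  d <- jsonlite::read_json(path)
  expect_true(all(c("mPrime", "hTrace", "eigenvalues", "k",
                    "componentSizes") %in% names(d)))
  expect_identical(as.integer(d$mPrime), nCommunities(res@sampling))
})
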