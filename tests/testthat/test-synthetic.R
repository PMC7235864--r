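test_that("config invariants are enforced with actionable errors", {
  expect_error(syntheticConfig(classProportions = c(0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(syntheticConfig(classProportions = c(-0.2, 0.6, 0.6)),
               "nonnegative")
  expect_error(syntheticConfig(nImages = 2), "nImages")
  expect_error(syntheticConfig(height = 800, width = 2400), "901x2201")
  expect_error(syntheticConfig(height = 1200, width = 2000), "901x2201")
})

test_that("three images with equal proportions give one per class", {
  ds <- generateDataset(
    syntheticConfig(nImages = 3, height = 901, width = 2201, seed = 1L),
    tempfile("synth3_"))
  expect_identical(sort(datasetManifest(ds)$label), sort(MOLAR_CLASSES))
  expect_identical(nrow(datasetManifest(ds)), 3L)
})

test_that("realized class counts deviate from floor(n*p) by at most 1", {
  cases <- list(list(n = 10, p = c(1, 1, 1) / 3),
                list(n = 47, p = c(0.5, 0.3, 0.2)),
                list(n = 9, p = c(0.7, 0.2, 0.1)),
                list(n = 150, p = c(1, 1, 1) / 3))
  for (cs in cases) {
    counts <- molarBoVW:::.classCounts(cs$n, cs$p)
    expect_identical(sum(counts), as.integer(cs$n))
    expect_true(all(counts - floor(cs$n * cs$p) <= 1))
    expect_true(all(counts >= floor(cs$n * cs$p)))
  }
})

test_that("noise-free rendering is bit-identical across runs", {
  cfg <- syntheticConfig(nImages = 3, height = 901, width = 2201,
                         noiseSigma = 0, mottlePoisson = FALSE, seed = 5L)
  a <- renderRadiograph(cfg, "R8_Lower", seed = 77L)
  b <- renderRadiograph(cfg, "R8_Lower", seed = 77L)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$sites, b$sites)
})

test_that("same seed reproduces a bit-identical dataset on disk", {
  cfg <- syntheticConfig(nImages = 3, height = 901, width = 2201, seed = 9L)
  d1 <- generateDataset(cfg, tempfile("rep1_"))
  d2 <- generateDataset(cfg, tempfile("rep2_"))
  expect_identical(datasetManifest(d1), datasetManifest(d2))
  expect_identical(datasetSites(d1), datasetSites(d2))
  for (p in datasetManifest(d1)$path) {
    expect_identical(readBin(file.path(datasetDir(d1), p), "raw", 1e7),
                     readBin(file.path(datasetDir(d2), p), "raw", 1e7))
  }
})

test_that("ground-truth sites sit inside the ROI band and match the label", {
  ds <- smallDataset()
  mask <- roiMask(makeRoiMask(1200, 2400))
  sites <- datasetSites(ds)
  expect_true(all(mask[cbind(sites$row, sites$col)]))
  mf <- datasetManifest(ds)
  for (i in seq_len(nrow(mf))) {
    s <- sites[sites$image == mf$path[i], ]
    expected <- switch(mf$label[i],
                       R8_Null = c(FALSE, FALSE, FALSE, FALSE),
                       R8_Lower = c(FALSE, FALSE, TRUE, TRUE),
                       R8_Upper_Lower = c(TRUE, TRUE, TRUE, TRUE))
    expect_identical(s$present[order(s$site)],
                     expected[order(c("upper_left", "upper_right",
                                      "lower_left", "lower_right"))])
  }
})

test_that("manifests round-trip and reject foreign labels", {
  m <- data.frame(path = c("a.png", "b.png", "c.png"),
                  label = c("R8_Lower", "R8_Null", "R8_Upper_Lower"))
  path <- tempfile(fileext = ".csv")
  writeManifest(m, path)
  expect_identical(length(readLines(path)), 4L)  # header + 3 rows
  back <- readManifest(path)
  expect_identical(back$path, m$path)
  expect_identical(back$label, m$label)

  writeLines(c("path,label", "x.png,R8_Sideways"), path)
  expect_error(readManifest(path), "R8_Sideways")
  expect_error(writeManifest(data.frame(path = "a", label = "bad"), path),
               "labels must be")
  expect_error(writeManifest(m[0, ], path), "non-empty")
})
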