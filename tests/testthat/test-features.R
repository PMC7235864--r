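test_that("method availability is explicit, never a silent fallback", {
  expect_identical(sort(availableFeatureMethods()), c("ORB", "SIFT"))
  expect_error(extractorConfig("BRISK"), "unknown feature method")
  cfg <- extractorConfig("SURF")  # configurable, but not extractable here
  img <- randomImage(1, 64)
  expect_error(extractFeatures(img, NULL, cfg), "not available")
})

test_that("degenerate inputs yield empty, well-shaped results", {
  const <- matrix(128L, 64, 64)
  f <- extractFeatures(const, NULL, extractorConfig("ORB"))
  expect_identical(nrow(f$descriptors), 0L)
  expect_identical(ncol(f$descriptors), 32L)
  expect_identical(nrow(f$keypoints), 0L)

  img <- randomImage(2, 64)
  allFalse <- new("RoiMask", mask = matrix(FALSE, 64, 64),
                  includedPixelCount = 0L)
  f2 <- extractFeatures(img, allFalse, extractorConfig("ORB"))
  expect_identical(nrow(f2$descriptors), 0L)
})

test_that("keypoints stay inside the mask with fixed descriptor width", {
  batch <- smallBatch()
  expect_identical(batch$d, 32L)
  mask <- roiMask(makeRoiMask(1200, 2400))
  for (kp in batch$keypoints) {
    if (nrow(kp) == 0) next
    expect_true(all(mask[cbind(round(kp$row), round(kp$col))]))
    expect_true(all(kp$orientation >= 0 & kp$orientation < 360))
  }
  expect_true(all(vapply(batch$descriptors, ncol, integer(1)) == 32L))
  expect_true(all(vapply(batch$descriptors, nrow, integer(1)) <= 500L))
})

test_that("extraction is deterministic and capped by response", {
  ds <- smallDataset()
  img <- readRadiograph(file.path(datasetDir(ds),
                                  datasetManifest(ds)$path[1]))
  edge <- preprocessChain(img)
  mask <- makeRoiMask(nrow(edge), ncol(edge))
  f1 <- extractFeatures(edge, mask, extractorConfig("ORB"))
  f2 <- extractFeatures(edge, mask, extractorConfig("ORB"))
  expect_identical(f1$descriptors, f2$descriptors)
  expect_identical(f1$keypoints, f2$keypoints)
  expect_true(all(diff(f1$keypoints$response) <= 1e-12))

  capped <- extractFeatures(edge, mask,
                            extractorConfig("ORB", maxKeypoints = 40L))
  expect_lte(nrow(capped$descriptors), 40L)
  expect_identical(capped$descriptors, f1$descriptors[1:40, ])
})

test_that("SIFT descriptors are 128-wide on a textured patch", {
  cfg <- smallSynthConfig()
  r <- renderRadiograph(cfg, "R8_Lower", seed = 21L)
  patch <- r$pixels[661:860, 656:855]  # around a textured lower site
  f <- extractFeatures(patch, NULL, extractorConfig("SIFT"))
  expect_gt(nrow(f$descriptors), 0L)
  expect_identical(ncol(f$descriptors), 128L)
})

test_that("ORB keypoint counts are stable under 90-degree rotation", {
  cfg <- smallSynthConfig()
  r <- renderRadiograph(cfg, "R8_Upper_Lower", seed = 31L)
  patch <- preprocessChain(r$pixels[661:860, 656:855])
  rot <- t(patch)[ncol(patch):1, ]  # 90-degree rotation
  storage.mode(rot) <- "integer"
  n1 <- nrow(extractFeatures(patch, NULL, extractorConfig("ORB"))$keypoints)
  n2 <- nrow(extractFeatures(rot, NULL, extractorConfig("ORB"))$keypoints)
  expect_gt(n1, 0)
  expect_lt(abs(n1 - n2) / max(n1, n2), 0.2)
})

test_that("affected sites attract keypoints near their centers", {
  batch <- smallBatch()
  ds <- smallDataset()
  sites <- datasetSites(ds)
  mf <- datasetManifest(ds)
  for (i in which(mf$label != "R8_Null")) {
    kp <- batch$keypoints[[i]]
    s <- sites[sites$image == mf$path[i] & sites$present, ]
    for (j in seq_len(nrow(s))) {
      dist <- sqrt((kp$row - s$row[j])^2 + (kp$col - s$col[j])^2)
      # a texture feature sits at each site center by construction, but
      # response ranking can prefer a neighbouring lattice feature; 20 px
      # is within one texture period of the center and well inside the
      # site's 48 px semi-minor axis
      expect_lt(min(dist), 20)
    }
  }
})

test_that("zero-keypoint images are flagged without derailing the batch", {
  dir <- tempfile("mixed_")
  dir.create(dir)
  ds <- smallDataset()
  file.copy(file.path(datasetDir(ds), datasetManifest(ds)$path[1]),
            file.path(dir, "real.png"))
  writeRadiograph(matrix(100L, 901, 2201), file.path(dir, "blank.png"))
  m <- data.frame(path = c("real.png", "blank.png", "missing.png"),
                  label = c("R8_Lower", "R8_Null", "R8_Null"))
  writeManifest(m, file.path(dir, "manifest.csv"))
  batch <- batchExtract(readManifest(file.path(dir, "manifest.csv")))
  expect_gt(batch$log$nKeypoints[1], 0L)
  expect_identical(batch$log$nKeypoints[2], 0L)
  expect_true(is.na(batch$log$error[2]))
  expect_false(is.na(batch$log$error[3]))  # unreadable image, isolated
  unlink(dir, recursive = TRUE)
})

test_that("descriptor containers round-trip bit-exactly and fail closed", {
  batch <- smallBatch()
  path <- tempfile(fileext = ".desc")
  saveDescriptors(batch, path)
  back <- loadDescriptors(path)
  expect_identical(back$descriptors, batch$descriptors)
  expect_identical(back$method, batch$method)
  expect_identical(back$log$nKeypoints, batch$log$nKeypoints)

  bytes <- readBin(path, "raw", file.size(path))
  writeBin(bytes[seq_len(length(bytes) - 5L)], path)
  expect_error(loadDescriptors(path), "corrupt")
  unlink(path)
})
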