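test_that("default mask area and half-open membership are exact", {
  m <- makeRoiMask(1200, 2400)
  expect_identical(includedPixels(m), 1026000L)  # (900-300) * (2200-490)
  msk <- roiMask(m)
  expect_false(msk[1, 1])            # (0, 0) excluded
  expect_true(msk[301, 491])         # (300, 490) included
  expect_false(msk[901, ncol(msk)])  # row 900 excluded (half-open)
  expect_false(msk[400, 2201])       # col 2200 excluded
})

test_that("mask rescales proportionally for other image sizes", {
  m <- makeRoiMask(600, 1200)  # half scale: [150,450) x [245,1100)
  msk <- roiMask(m)
  expect_identical(includedPixels(m), (450L - 150L) * (1100L - 245L))
  expect_true(msk[151, 246])
  expect_false(msk[150, 246])
  expect_true(msk[450, 1100])
  expect_false(msk[451, 246])

  # a 1 px-tall band collapses to nothing at small scales
  expect_error(makeRoiMask(2, 2400, roiSpec(rowStart = 300, rowEnd = 301)),
               "empty")
  expect_error(roiSpec(rowStart = 900, rowEnd = 300), "rowStart")
})

test_that("masking zeroes the outside, keeps dimensions, is idempotent", {
  img <- randomImage(5, 40, 60)
  allTrue <- new("RoiMask", mask = matrix(TRUE, 40, 60),
                 includedPixelCount = 2400L)
  expect_identical(applyMask(img, allTrue), img)

  allFalse <- new("RoiMask", mask = matrix(FALSE, 40, 60),
                  includedPixelCount = 0L)
  expect_true(all(applyMask(img, allFalse) == 0L))

  const <- matrix(128L, 1200, 2400)
  m <- makeRoiMask(1200, 2400)
  out <- applyMask(const, m)
  expect_identical(dim(out), dim(const))
  expect_equal(sum(as.numeric(out)), 128 * 1026000)
  expect_identical(applyMask(out, m), out)

  expect_error(applyMask(img[1:10, ], allTrue), "mask is")
})

test_that("the overlay preview reports the highlighted area", {
  img <- matrix(100L, 120, 240)
  m <- makeRoiMask(120, 240)
  path <- tempfile(fileext = ".png")
  n <- roiPreview(img, m, path)
  expect_identical(n, includedPixels(m))
  expect_true(file.exists(path))
  unlink(path)
})
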