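test_that("grayscale conversion uses the fixed luma weights", {
  g <- matrix(7L, 4, 5)
  expect_identical(toGrayscale(g), g)

  rgb <- array(0L, dim = c(2, 2, 3))
  rgb[, , 1] <- 90L; rgb[, , 2] <- 90L; rgb[, , 3] <- 90L
  expect_true(all(toGrayscale(rgb) == 90L))

  red <- array(0L, dim = c(1, 1, 3))
  red[1, 1, 1] <- 255L
  expect_identical(toGrayscale(red)[1, 1], 76L)  # round(0.299 * 255)

  two <- array(0L, dim = c(2, 2, 2))
  expect_error(toGrayscale(two), "channel count")
})

test_that("median filter removes impulses and preserves constants", {
  const <- matrix(42L, 8, 8)
  expect_identical(medianSmooth(const, 3), const)

  impulse <- matrix(0L, 5, 5)
  impulse[3, 3] <- 255L
  expect_true(all(medianSmooth(impulse, 3) == 0L))

  expect_error(medianSmooth(const, 4), "odd")
})

test_that("median filter equals the brute-force oracle", {
  for (s in 1:4) {
    img <- randomImage(s, 16)
    expect_identical(medianSmooth(img, 3), medianOracle(img, 3))
  }
  img <- randomImage(99, 12)
  expect_identical(medianSmooth(img, 5), medianOracle(img, 5))
})

test_that("bilateral filter matches its formula and keeps edges put", {
  const <- matrix(120L, 10, 10)
  expect_identical(bilateralSmooth(const), const)

  step <- cbind(matrix(0L, 16, 8), matrix(255L, 16, 8))
  out <- bilateralSmooth(step)
  for (i in 1:16) {
    expect_identical(which.max(diff(as.numeric(out[i, ]))),
                     which.max(diff(as.numeric(step[i, ]))))
  }

  for (s in 5:7) {
    img <- randomImage(s, 16)
    expect_lte(max(abs(bilateralSmooth(img) -
                       bilateralOracle(img, 9, 75, 75))), 1)
  }
  expect_error(filterParams(sigmaColor = 0), "sigma")
})

test_that("median and bilateral stay within the input range", {
  for (s in 11:14) {
    img <- randomImage(s, 16)
    for (out in list(medianSmooth(img, 3), bilateralSmooth(img))) {
      expect_gte(min(out), min(img))
      expect_lte(max(out), max(img))
    }
  }
})

test_that("Sobel gradients follow the kernel definition", {
  const <- matrix(17L, 6, 6)
  g <- sobelGradients(const)
  expect_true(all(g$gx == 0L) && all(g$gy == 0L))

  ramp <- matrix(rep(0:15, each = 16), 16, 16, byrow = TRUE)
  ramp <- t(ramp)  # I(r, c) = c - 1: unit column ramp
  storage.mode(ramp) <- "integer"
  g <- sobelGradients(ramp)
  expect_true(all(g$gx[2:15, 2:15] == 8L))
  expect_true(all(g$gy[2:15, 2:15] == 0L))

  for (s in 21:23) {
    img <- randomImage(s, 16)
    o <- sobelOracle(img)
    g <- sobelGradients(img)
    expect_identical(g$gx, o$gx)
    expect_identical(g$gy, o$gy)
  }
  expect_error(sobelGradients(matrix(1L, 2, 2)), "3x3")
})

test_that("gradient blending converts to uint8 by absolute value", {
  z <- matrix(0L, 4, 4)
  expect_true(all(blendGradients(list(gx = z, gy = z)) == 0L))

  img <- randomImage(31, 12)
  g <- sobelGradients(img)
  same <- blendGradients(list(gx = g$gx, gy = g$gx))
  expected <- pmin(abs(g$gx), 255L)
  storage.mode(expected) <- "integer"
  expect_identical(same, expected)

  big <- matrix(300L, 3, 3)
  out <- blendGradients(list(gx = big, gy = z[1:3, 1:3]))
  expect_true(all(out == 128L))  # clip(300) = 255; round(127.5) half-up

  expect_error(blendGradients(list(gx = z, gy = z[1:2, ])), "shapes differ")
})

test_that("the full chain is deterministic and zeroes flat images", {
  const <- matrix(200L, 12, 12)
  expect_true(all(preprocessChain(const) == 0L))

  img <- randomImage(41, 24)
  expect_identical(preprocessChain(img), preprocessChain(img))
  expect_identical(dim(preprocessChain(img)), dim(img))
})

test_that("edge response concentrates on phantom structure boundaries", {
  cfg <- smallSynthConfig()
  r <- renderRadiograph(cfg, "R8_Upper_Lower", seed = 3L)
  edge <- preprocessChain(r$pixels)
  perim <- numeric(0)
  for (i in seq_len(nrow(r$sites))) {
    th <- seq(0, 2 * pi, length.out = 90)
    rr <- pmax(1, pmin(nrow(edge), round(r$sites$row[i] + 70 * sin(th))))
    cc <- pmax(1, pmin(ncol(edge), round(r$sites$col[i] + 48 * cos(th))))
    perim <- c(perim, edge[cbind(rr, cc)])
  }
  expect_gt(mean(perim), mean(edge))
})
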