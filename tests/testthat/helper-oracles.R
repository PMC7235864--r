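# Brute-force reference implementations of the windowed filters, written
# as literal double loops over the operator definitions. They stay
# independent of the package's C++ path.

reflect101Index <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
  }
  i
}

medianOracle <- function(img, kernel) {
  r <- kernel %/% 2
  out <- img
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      v <- integer(0)
      for (di in -r:r) for (dj in -r:r)
        v <- c(v, img[reflect101Index(i + di, nrow(img)),
                      reflect101Index(j + dj, ncol(img))])
      out[i, j] <- sort(v)[(kernel * kernel) %/% 2 + 1]
    }
  }
  out
}

bilateralOracle <- function(img, diameter, sigmaColor, sigmaSpace) {
  r <- diameter %/% 2
  out <- img
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      num <- 0; den <- 0
      for (di in -r:r) for (dj in -r:r) {
        v <- img[reflect101Index(i + di, nrow(img)),
                 reflect101Index(j + dj, ncol(img))]
        wgt <- exp(-(di^2 + dj^2) / (2 * sigmaSpace^2)) *
          exp(-((v - img[i, j])^2) / (2 * sigmaColor^2))
        num <- num + wgt * v
        den <- den + wgt
      }
      out[i, j] <- floor(num / den + 0.5)
    }
  }
  out
}

sobelOracle <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # [[-1,0,1],[-2,0,2],[-1,0,1]]
  gx <- img; gy <- img
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      sx <- 0; sy <- 0
      for (di in -1:1) for (dj in -1:1) {
        v <- img[reflect101Index(i + di, nrow(img)),
                 reflect101Index(j + dj, ncol(img))]
        sx <- sx + kx[di + 2, dj + 2] * v
        sy <- sy + kx[dj + 2, di + 2] * v
      }
      gx[i, j] <- sx; gy[i, j] <- sy
    }
  }
  storage.mode(gx) <- "integer"
  storage.mode(gy) <- "integer"
  list(gx = gx, gy = gy)
}

# exhaustive nearest-center tally, the reference for encodeBovw()
encodeOracle <- function(X, centers) {
  counts <- integer(nrow(centers))
  for (i in seq_len(nrow(X))) {
    d2 <- colSums((t(centers) - X[i, ])^2)
    counts[which.min(d2)] <- counts[which.min(d2)] + 1L
  }
  counts
}

randomImage <- function(seed, h = 16, w = h) {
  set.seed(seed)
  matrix(as.integer(sample(0:255, h * w, replace = TRUE)), h, w)
}
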