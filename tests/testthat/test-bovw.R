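test_that("K = n distinct points gives zero inertia at the inputs", {
  set.seed(3)
  X <- matrix(stats::rnorm(12 * 4), 12, 4)
  v <- buildVocabulary(X, K = 12, seed = 1L)
  expect_equal(vocabInertia(v), 0)
  sortRows <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(sortRows(vocabCenters(v)), sortRows(X), tolerance = 1e-12)
})

test_that("well-separated clusters are recovered at their sample means", {
  set.seed(17)
  a <- matrix(stats::rnorm(20 * 3, mean = 0, sd = 0.05), 20, 3)
  b <- matrix(stats::rnorm(20 * 3, mean = 10, sd = 0.05), 20, 3)
  v <- buildVocabulary(rbind(a, b), K = 2, seed = 4L)
  got <- vocabCenters(v)[order(vocabCenters(v)[, 1]), ]
  want <- rbind(colMeans(a), colMeans(b))
  expect_lt(max(abs(got - want)), 0.1)

  # independent cross-check: stats::kmeans lands on the same means
  km <- stats::kmeans(rbind(a, b), centers = 2, nstart = 5)
  ref <- km$centers[order(km$centers[, 1]), ]
  expect_lt(max(abs(got - ref)), 0.1)
})

test_that("the returned centers are a Lloyd fixed point", {
  set.seed(23)
  X <- matrix(stats::rnorm(60 * 8), 60, 8)
  v <- buildVocabulary(X, K = 5, seed = 9L)
  centers <- vocabCenters(v)
  assign <- integer(60)
  for (i in 1:60) {
    d2 <- colSums((t(centers) - X[i, ])^2)
    assign[i] <- which.min(d2)
  }
  for (k in unique(assign)) {
    expect_equal(centers[k, ], colMeans(X[assign == k, , drop = FALSE]),
                 tolerance = 1e-3)
  }
})

test_that("Lloyd inertia never increases and runs are seed-deterministic", {
  set.seed(8)
  X <- matrix(stats::runif(200 * 6, 0, 255), 200, 6)
  v1 <- buildVocabulary(X, K = 10, seed = 5L)
  v2 <- buildVocabulary(X, K = 10, seed = 5L)
  expect_true(all(diff(v1@inertiaHistory) <= 1e-6))
  expect_identical(vocabCenters(v1), vocabCenters(v2))
  v3 <- buildVocabulary(X, K = 10, seed = 6L)
  expect_false(identical(vocabCenters(v1), vocabCenters(v3)))

  expect_error(buildVocabulary(X, K = 500, seed = 1L), "smaller K")
})

test_that("encoding matches the exhaustive nearest-center oracle", {
  for (s in 1:10) {
    set.seed(s)
    K <- sample(2:8, 1)
    d <- sample(c(4L, 8L, 16L), 1)
    centers <- matrix(stats::runif(K * d, 0, 255), K, d)
    v <- new("Vocabulary", centers = centers, method = "",
             kmeansSeed = 0L, inertia = 0, inertiaHistory = numeric(0))
    X <- matrix(stats::runif(30 * d, 0, 255), 30, d)
    h <- encodeBovw(X, v, normalize = FALSE)
    expect_identical(as.integer(h), encodeOracle(X, centers))
    expect_identical(sum(h), 30)  # histogram conservation
  }
})

test_that("encode handles exact hits, empties, ties and normalisation", {
  centers <- rbind(c(0, 0), c(10, 10), c(20, 20))
  v <- new("Vocabulary", centers = centers, method = "", kmeansSeed = 0L,
           inertia = 0, inertiaHistory = numeric(0))
  h <- encodeBovw(centers[c(2, 2, 3), ], v, normalize = FALSE)
  expect_identical(as.numeric(h), c(0, 2, 1))

  empty <- encodeBovw(matrix(0, 0, 2), v, normalize = TRUE)
  expect_identical(as.numeric(empty), c(0, 0, 0))
  expect_false(attr(empty, "normalized"))

  tie <- encodeBovw(matrix(c(5, 5), 1, 2), v, normalize = FALSE)
  expect_identical(as.numeric(tie), c(1, 0, 0))  # lowest index wins

  norm <- encodeBovw(matrix(c(0, 0, 9, 9), 2, 2, byrow = TRUE), v)
  expect_equal(sum(norm), 1)

  expect_error(encodeBovw(matrix(0, 2, 5), v), "dimension 5")
})

test_that("vocabularies round-trip bit-exactly and fail closed", {
  set.seed(2)
  X <- matrix(stats::rnorm(50 * 32), 50, 32)
  v <- buildVocabulary(X, K = 7, seed = 3L, method = "ORB")
  path <- tempfile(fileext = ".bovw")
  saveVocabulary(v, path)
  back <- loadVocabulary(path)
  expect_identical(vocabCenters(back), vocabCenters(v))
  expect_identical(vocabMethod(back), "ORB")
  expect_identical(back@kmeansSeed, v@kmeansSeed)
  # inertia travels in the JSON header: near-exact, not bit-exact
  expect_equal(vocabInertia(back), vocabInertia(v), tolerance = 1e-12)

  bytes <- readBin(path, "raw", file.size(path))
  writeBin(bytes[seq_len(length(bytes) - 9L)], path)
  expect_error(loadVocabulary(path), "corrupt")

  # a SIFT-shaped vocabulary cannot encode ORB-width descriptors
  vs <- new("Vocabulary", centers = matrix(0, 4, 128), method = "SIFT",
            kmeansSeed = 0L, inertia = 0, inertiaHistory = numeric(0))
  expect_error(encodeBovw(matrix(0L, 3, 32), vs), "128")
  unlink(path)
})

test_that("encodeBovwSet produces a labelled words-by-images container", {
  batch <- smallBatch()
  v <- buildVocabulary(batch$descriptors, K = 25, seed = 2L, method = "ORB")
  bset <- encodeBovwSet(batch, v)
  expect_s4_class(bset, "BovwSet")
  expect_identical(dim(bovwCounts(bset)), c(25L, 6L))
  expect_identical(bovwLabels(bset), batch$log$label)
  sums <- colSums(bovwCounts(bset))
  expect_true(all(abs(sums[batch$log$nKeypoints > 0] - 1) < 1e-9))

  vs <- new("Vocabulary", centers = matrix(0, 4, 128), method = "SIFT",
            kmeansSeed = 0L, inertia = 0, inertiaHistory = numeric(0))
  expect_error(encodeBovwSet(batch, vs), "SIFT")
})
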