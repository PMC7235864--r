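test_that("stratified folds partition the data within one of balance", {
  y <- rep(MOLAR_CLASSES, each = 10)
  f <- makeFolds(y, 10, seed = 1L)
  expect_identical(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 3L))
  expect_true(all(table(y, f) == 1L))  # one item per class per fold

  # property: sizes and per-class counts within 1, for assorted shapes
  for (s in 1:6) {
    set.seed(s)
    n <- sample(25:90, 1)
    y <- sample(MOLAR_CLASSES, n, replace = TRUE,
                prob = c(0.2, 0.5, 0.3))
    if (min(table(y)) < 1) next
    k <- sample(c(5L, 10L), 1)
    f <- makeFolds(y, k, seed = s)
    expect_identical(length(f), n)        # a partition: every item placed
    expect_true(all(f %in% seq_len(k)))
    expect_lte(diff(range(table(factor(f, levels = 1:k)))), 1L)
    percls <- table(y, factor(f, levels = 1:k))
    expect_true(all(apply(percls, 1, function(r) diff(range(r)) <= 1)))
  }
})

test_that("447 items split 10 ways as seven 45s and three 44s", {
  y <- rep(MOLAR_CLASSES, each = 149)
  f <- makeFolds(y, 10, seed = 42L)
  expect_identical(sort(as.integer(table(f)), decreasing = TRUE),
                   c(rep(45L, 7), rep(44L, 3)))
  expect_error(makeFolds(y[1:5], 10), "10 folds from 5")
})

test_that("all six classifiers memorise a separable toy problem", {
  X <- rbind(matrix(rep(c(1, 0, 0, 0), 8), 8, 4, byrow = TRUE),
             matrix(rep(c(0, 0, 1, 0), 8), 8, 4, byrow = TRUE))
  y <- rep(c("R8_Lower", "R8_Null"), each = 8)
  for (nm in classifierNames()) {
    model <- trainClassifier(nm, X, y, seed = 1L)
    expect_identical(as.character(predict(model, X)), y)
  }
  expect_error(trainClassifier("naive_bayes", X, y), "valid names")
})

test_that("constant-label training predicts that label everywhere", {
  X <- matrix(stats::runif(40), 10, 4)
  for (nm in c("decision_tree", "svm_rbf", "mlp")) {
    model <- trainClassifier(nm, X, rep("R8_Null", 10), seed = 1L)
    expect_true(all(predict(model, X) == "R8_Null"))
  }
})

test_that("seeded stochastic learners give identical predictions", {
  set.seed(50)
  X <- matrix(stats::runif(60 * 6), 60, 6)
  y <- rep(MOLAR_CLASSES, each = 20)
  probe <- matrix(stats::runif(30 * 6), 30, 6)
  for (nm in c("random_forest", "gradient_boosting", "mlp")) {
    m1 <- trainClassifier(nm, X, y, seed = 7L)
    m2 <- trainClassifier(nm, X, y, seed = 7L)
    expect_identical(predict(m1, probe), predict(m2, probe))
  }
})

test_that("cross-validation separates disjoint-support histograms", {
  set.seed(4)
  n <- 60
  y <- rep(MOLAR_CLASSES, each = n / 3)
  X <- matrix(0, n, 9)
  for (i in seq_len(n)) {
    block <- (match(y[i], MOLAR_CLASSES) - 1) * 3
    X[i, block + (1:3)] <- stats::runif(3, 0.5, 1)
  }
  cv <- crossValidate(X, y, classifiers = "decision_tree", nFolds = 10,
                      seed = 2L)
  expect_equal(meanAccuracy(cv$results$decision_tree), 1.0)
})

test_that("permuted labels collapse accuracy to chance", {
  set.seed(5)
  n <- 150
  y <- rep(MOLAR_CLASSES, each = n / 3)
  X <- matrix(0, n, 9)
  for (i in seq_len(n))
    X[i, (match(y[i], MOLAR_CLASSES) - 1) * 3 + (1:3)] <- 1
  yp <- sample(y)
  cv <- crossValidate(X, yp, classifiers = "decision_tree", nFolds = 10,
                      seed = 3L)
  acc <- meanAccuracy(cv$results$decision_tree)
  expect_gte(acc, 0.20)
  expect_lte(acc, 0.47)
})

test_that("reports are recomputable, paired and reproducible", {
  set.seed(6)
  X <- matrix(stats::runif(45 * 8), 45, 8)
  y <- rep(MOLAR_CLASSES, each = 15)
  cv1 <- crossValidate(X, y, classifiers = c("decision_tree", "logistic"),
                       nFolds = 5, seed = 11L)
  cv2 <- crossValidate(X, y, classifiers = c("decision_tree", "logistic"),
                       nFolds = 5, seed = 11L)
  for (nm in names(cv1$results)) {
    r <- cv1$results[[nm]]
    expect_equal(meanAccuracy(r), mean(foldAccuracies(r)), tolerance = 1e-12)
    expect_equal(sdAccuracy(r),
                 sqrt(mean((foldAccuracies(r) - mean(foldAccuracies(r)))^2)),
                 tolerance = 1e-12)
    expect_identical(foldAccuracies(r), foldAccuracies(cv2$results[[nm]]))
    # paired protocol: every classifier sees the same folds
    expect_identical(foldAssignment(r),
                     foldAssignment(cv1$results$decision_tree))
  }
  expect_identical(cv1$foldAssignment, cv2$foldAssignment)
})

test_that("histogram-width mismatches are caught before prediction", {
  X <- matrix(stats::runif(30), 10, 3)
  m <- trainClassifier("decision_tree", X, rep(MOLAR_CLASSES[1:2], 5),
                       seed = 1L)
  expect_error(predict(m, matrix(0, 2, 5)), "3-bin")
})
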