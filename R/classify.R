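#' The six benchmark classifiers
#'
#' @return Character vector of classifier names accepted by
#'   [trainClassifier()]: multinomial logistic regression, RBF-kernel
#'   support vector machine, a one-hidden-layer (100 ReLU units)
#'   multilayer perceptron, decision tree, gradient boosting and random
#'   forest.
#' @export
classifierNames <- function() {
  c("logistic", "svm_rbf", "mlp", "decision_tree",
    "gradient_boosting", "random_forest")
}

#' Pinned hyperparameter defaults for the six classifiers
#'
#' The published comparison names the classifiers but not their
#' settings, so every remaining hyperparameter is pinned here and can be
#' overridden via the `hyper` argument of [trainClassifier()].
#'
#' @return Named list of per-classifier default settings.
#' @export
classifierDefaults <- function() {
  list(
    logistic = list(maxit = 200L, decay = 0),
    svm_rbf = list(cost = 1, gamma = NULL),  # NULL -> 1/ncol(x)
    mlp = list(hidden = 100L, epochs = 200L, batch = 32L, lr = 1e-3),
    decision_tree = list(minsplit = 10L, cp = 0.01, maxdepth = 30L),
    gradient_boosting = list(nrounds = 100L, eta = 0.1, max_depth = 3L),
    random_forest = list(ntree = 200L)
  )
}

#' Stratified fold assignment for k-fold cross-validation
#'
#' Within each class the (seeded) shuffled members are dealt round-robin
#' into folds, with the dealing pointer carried across classes so that
#' total fold sizes also differ by at most one. Deterministic given the
#' seed.
#'
#' @param labels character or factor vector of class labels.
#' @param nFolds number of folds (default 10).
#' @param seed integer seed.
#' @return Integer vector of fold indices in `1..nFolds`, one per item.
#' @export
makeFolds <- function(labels, nFolds = 10L, seed = 0L) {
  n <- length(labels)
  nFolds <- as.integer(nFolds)
  if (n < nFolds)
    stop("cannot make ", nFolds, " folds from ", n, " items")
  if (nFolds < 2L) stop("need at least 2 folds")
  y <- factor(labels)
  if (any(table(y) < 1L)) stop("every class must have at least one item")
  set.seed(as.integer(seed %% 2147483647))
  fold <- integer(n)
  ptr <- 0L
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((ptr + seq_along(idx) - 1L) %% nFolds) + 1L
    ptr <- (ptr + length(idx)) %% nFolds
  }
  fold
}

.histColnames <- function(K) paste0("w", seq_len(K))

#' Train one of the six benchmark classifiers
#'
#' @param name one of [classifierNames()].
#' @param X n x K numeric histogram matrix.
#' @param y class labels (factor or character).
#' @param hyper named list overriding entries of [classifierDefaults()]
#'   for this classifier.
#' @param seed integer seed for the stochastic learners (forest,
#'   boosting, MLP initialisation).
#' @param method optional extractor-method tag recorded in the model for
#'   compatibility checks at prediction time.
#' @return A [BovwModel-class] usable with [predict()].
#' @export
trainClassifier <- function(name, X, y, hyper = list(), seed = 0L,
                            method = NA_character_) {
  if (!name %in% classifierNames())
    stop("unknown classifier '", name, "'; valid names: ",
         paste(classifierNames(), collapse = ", "))
  if (!all(is.finite(X))) stop("histograms must be finite")
  y <- droplevels(factor(y))
  X <- as.matrix(X)
  colnames(X) <- .histColnames(ncol(X))
  h <- utils::modifyList(classifierDefaults()[[name]], hyper)
  seed <- as.integer(seed %% 2147483647)
  set.seed(seed)
  fit <- if (nlevels(y) == 1L) {
    structure(list(level = levels(y)), class = "molarConstantFit")
  } else switch(name,
    logistic = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- y
      nnet::multinom(.y ~ ., data = df, maxit = h$maxit, decay = h$decay,
                     MaxNWts = 1e6, trace = FALSE)
    },
    svm_rbf = e1071::svm(
      x = X, y = y, kernel = "radial", cost = h$cost,
      gamma = if (is.null(h$gamma)) 1 / ncol(X) else h$gamma,
      scale = FALSE),
    mlp = .mlpFit(X, y, hidden = h$hidden, epochs = h$epochs,
                  batch = h$batch, lr = h$lr, seed = seed),
    decision_tree = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     minsplit = h$minsplit, cp = h$cp,
                     maxdepth = h$maxdepth, xval = 0L))
    },
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "multi:softmax", num_class = nlevels(y),
                    eta = h$eta, max_depth = h$max_depth, nthread = 1L,
                    seed = seed),
      data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L,
                                  nthread = 1L),
      nrounds = h$nrounds, verbose = 0L),
    random_forest = randomForest::randomForest(x = X, y = y,
                                               ntree = h$ntree)
  )
  new("BovwModel", name = name, fit = fit, levels = levels(y),
      dim = ncol(X), method = as.character(method), seed = seed)
}

#' Predict labels for histogram rows
#'
#' @param object a [BovwModel-class].
#' @param newdata m x K histogram matrix with the K the model was
#'   trained on.
#' @param ... ignored.
#' @return Factor of predicted labels, one per row of `newdata`.
#' @export
setMethod("predict", "BovwModel", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object@dim)
    stop("model expects ", object@dim, "-bin histograms, got ", ncol(X))
  colnames(X) <- .histColnames(ncol(X))
  lev <- object@levels
  fit <- object@fit
  out <- if (inherits(fit, "molarConstantFit")) {
    rep(fit$level, nrow(X))
  } else switch(object@name,
    logistic = as.character(predict(fit, newdata = data.frame(
      X, check.names = FALSE), type = "class")),
    svm_rbf = as.character(predict(fit, X)),
    mlp = as.character(.mlpPredict(fit, X)),
    decision_tree = as.character(predict(fit, newdata = data.frame(
      X, check.names = FALSE), type = "class")),
    gradient_boosting = lev[predict(fit, xgboost::xgb.DMatrix(
      X, nthread = 1L)) + 1L],
    random_forest = as.character(predict(fit, X))
  )
  factor(out, levels = lev)
})

#' Cross-validate classifiers on a histogram set
#'
#' Runs stratified k-fold cross-validation: for each classifier, train
#' on k-1 folds and score accuracy on the held-out fold, rotating
#' through all folds. All classifiers share the identical fold
#' assignment so the comparison is paired. A training failure in one
#' fold marks that classifier's result `"failed"` (accuracy `NA` in the
#' affected folds) without touching the others.
#'
#' @param x a [BovwSet-class], or an n x K histogram matrix.
#' @param labels class labels (taken from `x` when it is a BovwSet).
#' @param classifiers character vector of [classifierNames()] entries.
#' @param nFolds number of folds (default 10).
#' @param seed integer run seed; per-classifier, per-fold training seeds
#'   derive from it via [deriveSeed()].
#' @param hyper optional named list of per-classifier hyper overrides.
#' @return A list with `results` (named list of [CvResult-class]),
#'   `report` (data.frame: classifier, meanAccuracy, sdAccuracy,
#'   `accuracy` formatted as mean+/-sd), `foldAssignment`, and
#'   `confusion` (summed hold-out confusion matrix per classifier).
#' @export
crossValidate <- function(x, labels = NULL, classifiers = classifierNames(),
                          nFolds = 10L, seed = 0L, hyper = list()) {
  if (is(x, "BovwSet")) {
    labels <- bovwLabels(x)
    X <- t(bovwCounts(x))
  } else {
    X <- as.matrix(x)
  }
  if (is.null(labels)) stop("labels are required")
  y <- droplevels(factor(labels))
  n <- nrow(X)
  stopifnot(length(y) == n)
  fold <- makeFolds(y, nFolds, deriveSeed(seed, "folds"))
  ids <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(n))
  names(fold) <- ids
  results <- list()
  confusion <- list()
  for (nm in classifiers) {
    acc <- rep(NA_real_, nFolds)
    cm <- matrix(0L, nlevels(y), nlevels(y),
                 dimnames = list(truth = levels(y), predicted = levels(y)))
    failed <- FALSE
    for (f in seq_len(nFolds)) {
      test <- fold == f
      res <- tryCatch({
        model <- trainClassifier(nm, X[!test, , drop = FALSE], y[!test],
                                 hyper = hyper[[nm]] %||% list(),
                                 seed = deriveSeed(seed, paste0(nm, f)))
        pred <- predict(model, X[test, , drop = FALSE])
        list(acc = mean(pred == y[test]),
             cm = table(truth = y[test], predicted = pred))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- TRUE
      } else {
        acc[f] <- res$acc
        cm <- cm + unclass(res$cm)
      }
    }
    ok <- acc[!is.na(acc)]
    results[[nm]] <- new("CvResult", classifier = nm,
                         foldAccuracies = acc,
                         meanAccuracy = if (length(ok)) mean(ok) else NA_real_,
                         sdAccuracy = if (length(ok))
                           sqrt(mean((ok - mean(ok))^2)) else NA_real_,
                         foldAssignment = fold,
                         seed = as.integer(seed),
                         status = if (failed) "failed" else "ok")
    confusion[[nm]] <- cm
  }
  report <- data.frame(
    classifier = names(results),
    meanAccuracy = vapply(results, meanAccuracy, numeric(1)),
    sdAccuracy = vapply(results, sdAccuracy, numeric(1)),
    stringsAsFactors = FALSE)
  report$accuracy <- sprintf("%.1f%%+/-%.1f%%", 100 * report$meanAccuracy,
                             100 * report$sdAccuracy)
  rownames(report) <- NULL
  list(results = results, report = report, foldAssignment = fold,
       confusion = confusion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' End-to-end prediction for a single radiograph
#'
#' Runs preprocess, ROI mask, feature extraction, BoVW encoding and
#' classification on one image. Method and dimension compatibility
#' between model, vocabulary and extractor are checked before any
#' computation. A blank image (zero keypoints) still yields a
#' prediction, flagged `lowEvidence`.
#'
#' @param model a [BovwModel-class].
#' @param vocab the [Vocabulary-class] the model was trained against.
#' @param imagePath path of the radiograph (PNG/TIFF).
#' @param params a [filterParams()].
#' @param spec a [roiSpec()].
#' @param config an [extractorConfig()]; its method must match the
#'   vocabulary's.
#' @param normalize L1-normalise the histogram (must match training).
#' @return List with `label`, `histogram`, `nKeypoints`, `lowEvidence`.
#' @export
predictImage <- function(model, vocab, imagePath, params = filterParams(),
                         spec = roiSpec(), config = extractorConfig(),
                         normalize = TRUE) {
  if (nzchar(vocab@method) && !identical(config$method, vocab@method))
    stop("extractor method ", config$method,
         " is incompatible with a ", vocab@method, " vocabulary")
  if (!is.na(model@method) && nzchar(model@method) &&
      !identical(model@method, vocab@method))
    stop("model was trained on ", model@method,
         " histograms; vocabulary is ", vocab@method)
  if (model@dim != vocabK(vocab))
    stop("model expects ", model@dim, "-bin histograms but vocabulary has ",
         vocabK(vocab), " words")
  img <- readRadiograph(imagePath)
  edge <- preprocessChain(img, params)
  mask <- makeRoiMask(nrow(edge), ncol(edge), spec)
  feat <- extractFeatures(edge, mask, config)
  h <- encodeBovw(feat$descriptors, vocab, normalize)
  pred <- predict(model, matrix(h, nrow = 1))
  list(label = as.character(pred), histogram = h,
       nKeypoints = nrow(feat$descriptors),
       lowEvidence = nrow(feat$descriptors) == 0L)
}
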