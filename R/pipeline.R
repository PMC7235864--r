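#' Assemble a full pipeline configuration
#'
#' Houses every stage's constants: the smoothing chain (median kernel 3;
#' bilateral diameter 9, sigmas 75/75), the ROI band, the extractor, the
#' vocabulary size (published recipe 2800; synthetic preset 200),
#' histogram normalisation, the fold count and classifier list, and one
#' global seed from which every stage seed derives ([deriveSeed()]).
#'
#' @param filterParams a [filterParams()].
#' @param roiSpec a [roiSpec()].
#' @param extractor an [extractorConfig()].
#' @param vocabK number of visual words.
#' @param normalizeHistograms L1-normalise histograms before
#'   classification.
#' @param nFolds cross-validation folds.
#' @param classifiers subset of [classifierNames()].
#' @param globalSeed integer seed reproducing the whole run.
#' @param strictCv build the vocabulary on training descriptors only
#'   within each fold (`TRUE`) or once globally before classification
#'   (`FALSE`, the published protocol; the global variant leaks
#'   descriptor information across folds, hence the flag).
#' @param synthetic optional [syntheticConfig()] for runs that generate
#'   their own data.
#' @param useEdgeImage extract features from the blended edge image
#'   (`TRUE`, the published ordering) or from the smoothed pre-Sobel
#'   image.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(filterParams = molarBoVW::filterParams(),
                           roiSpec = molarBoVW::roiSpec(),
                           extractor = extractorConfig(),
                           vocabK = 2800L, normalizeHistograms = TRUE,
                           nFolds = 10L,
                           classifiers = classifierNames(),
                           globalSeed = 42L, strictCv = FALSE,
                           synthetic = NULL, useEdgeImage = TRUE) {
  stopifnot(inherits(filterParams, "FilterParams"),
            is(roiSpec, "RoiSpec"),
            inherits(extractor, "ExtractorConfig"))
  if (!all(classifiers %in% classifierNames()))
    stop("unknown classifier(s): ",
         paste(setdiff(classifiers, classifierNames()), collapse = ", "))
  if (vocabK < 1L) stop("vocabK must be positive")
  if (!is.null(synthetic)) stopifnot(is(synthetic, "SyntheticConfig"))
  structure(list(filterParams = filterParams, roiSpec = roiSpec,
                 extractor = extractor, vocabK = as.integer(vocabK),
                 normalizeHistograms = isTRUE(normalizeHistograms),
                 nFolds = as.integer(nFolds), classifiers = classifiers,
                 globalSeed = as.integer(globalSeed),
                 strictCv = isTRUE(strictCv), synthetic = synthetic,
                 useEdgeImage = isTRUE(useEdgeImage)),
            class = "PipelineConfig")
}

#' The desk-scale synthetic preset
#'
#' 150 balanced synthetic images at 1200 x 2400, ORB features, a
#' 200-word vocabulary and seed 42 — small enough to run on one CPU in
#' minutes while still exercising every pipeline stage.
#'
#' @param nImages,vocabK,globalSeed overrides of the preset values.
#' @param ... further arguments passed to [pipelineConfig()].
#' @return A `PipelineConfig`.
#' @export
syntheticPreset <- function(nImages = 150L, vocabK = 200L,
                            globalSeed = 42L, ...) {
  pipelineConfig(vocabK = vocabK, globalSeed = globalSeed,
                 synthetic = syntheticConfig(nImages = nImages,
                                             seed = globalSeed), ...)
}

# flatten a config into plain lists for the report snapshot
.configSnapshot <- function(config) {
  rs <- config$roiSpec
  list(filter_params = unclass(config$filterParams),
       roi_spec = list(row_start = rs@rowStart, row_end = rs@rowEnd,
                       col_start = rs@colStart, col_end = rs@colEnd,
                       reference_height = rs@refHeight,
                       reference_width = rs@refWidth),
       extractor = unclass(config$extractor),
       vocab_k = config$vocabK,
       normalize_histograms = config$normalizeHistograms,
       n_folds = config$nFolds, classifiers = config$classifiers,
       global_seed = config$globalSeed, strict_cv = config$strictCv,
       use_edge_image = config$useEdgeImage,
       synthetic = if (is.null(config$synthetic)) NULL else {
         s <- config$synthetic
         list(n_images = s@nImages, class_proportions = s@classProportions,
              height = s@height, width = s@width, noise_sigma = s@noiseSigma,
              mottle_poisson = s@mottlePoisson,
              molar_contrast = s@molarContrast, tilt_range = s@tiltRange,
              seed = s@seed)
       })
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file must use exactly the snapshot schema written into every
#' report (`filter_params`, `roi_spec`, `extractor`, `vocab_k`,
#' `normalize_histograms`, `n_folds`, `classifiers`, `global_seed`,
#' `strict_cv`, `use_edge_image`, `synthetic`); unknown keys are errors
#' so a typo cannot silently revert a constant to its default.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON")
  known <- c("filter_params", "roi_spec", "extractor", "vocab_k",
             "normalize_histograms", "n_folds", "classifiers",
             "global_seed", "strict_cv", "use_edge_image", "synthetic")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  checkSub <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown ", where, " key(s): ", paste(extra, collapse = ", "))
    x
  }
  fp <- checkSub(raw$filter_params %||% list(),
                 c("medianKernel", "bilateralDiameter", "sigmaColor",
                   "sigmaSpace", "blendWx", "blendWy"), "filter_params")
  rsRaw <- checkSub(raw$roi_spec %||% list(),
                    c("row_start", "row_end", "col_start", "col_end",
                      "reference_height", "reference_width"), "roi_spec")
  exRaw <- checkSub(raw$extractor %||% list(),
                    c("method", "maxKeypoints", "detectorParams", "seed"),
                    "extractor")
  syRaw <- raw$synthetic
  if (!is.null(syRaw))
    syRaw <- checkSub(syRaw, c("n_images", "class_proportions", "height",
                               "width", "noise_sigma", "mottle_poisson",
                               "molar_contrast", "tilt_range", "seed"),
                      "synthetic")
  rsArgs <- list(rowStart = rsRaw$row_start, rowEnd = rsRaw$row_end,
                 colStart = rsRaw$col_start, colEnd = rsRaw$col_end,
                 refHeight = rsRaw$reference_height,
                 refWidth = rsRaw$reference_width)
  syn <- if (is.null(syRaw)) NULL else {
    syArgs <- list(nImages = syRaw$n_images,
                   classProportions = syRaw$class_proportions,
                   height = syRaw$height, width = syRaw$width,
                   noiseSigma = syRaw$noise_sigma,
                   mottlePoisson = syRaw$mottle_poisson,
                   molarContrast = syRaw$molar_contrast,
                   tiltRange = syRaw$tilt_range, seed = syRaw$seed)
    do.call(syntheticConfig, syArgs[!vapply(syArgs, is.null, logical(1))])
  }
  args <- list(
    filterParams = do.call(filterParams, fp),
    roiSpec = do.call(roiSpec, rsArgs[!vapply(rsArgs, is.null, logical(1))]),
    extractor = do.call(extractorConfig, exRaw),
    vocabK = raw$vocab_k, normalizeHistograms = raw$normalize_histograms,
    nFolds = raw$n_folds, classifiers = raw$classifiers,
    globalSeed = raw$global_seed, strictCv = raw$strict_cv,
    synthetic = syn, useEdgeImage = raw$use_edge_image)
  do.call(pipelineConfig, args[!vapply(args, is.null, logical(1))])
}

# per-fold vocabulary variant: no descriptor information crosses folds
.crossValidateStrict <- function(batch, labels, config) {
  y <- droplevels(factor(labels))
  nFolds <- config$nFolds
  fold <- makeFolds(y, nFolds, deriveSeed(config$globalSeed, "folds"))
  names(fold) <- make.unique(basename(batch$log$path))
  acc <- sapply(config$classifiers, function(nm) rep(NA_real_, nFolds))
  for (f in seq_len(nFolds)) {
    test <- fold == f
    vocab <- buildVocabulary(batch$descriptors[!test], config$vocabK,
                             seed = deriveSeed(config$globalSeed,
                                               paste0("kmeans", f)),
                             method = batch$method)
    H <- t(vapply(batch$descriptors, function(m)
      as.numeric(encodeBovw(m, vocab, config$normalizeHistograms)),
      numeric(config$vocabK)))
    for (nm in config$classifiers) {
      res <- tryCatch({
        model <- trainClassifier(
          nm, H[!test, , drop = FALSE], y[!test],
          seed = deriveSeed(config$globalSeed, paste0(nm, f)),
          method = batch$method)
        mean(predict(model, H[test, , drop = FALSE]) == y[test])
      }, error = function(e) NA_real_)
      acc[f, nm] <- res
    }
  }
  results <- lapply(config$classifiers, function(nm) {
    a <- acc[, nm]
    ok <- a[!is.na(a)]
    new("CvResult", classifier = nm, foldAccuracies = as.numeric(a),
        meanAccuracy = if (length(ok)) mean(ok) else NA_real_,
        sdAccuracy = if (length(ok)) sqrt(mean((ok - mean(ok))^2))
                     else NA_real_,
        foldAssignment = fold, seed = config$globalSeed,
        status = if (anyNA(a)) "failed" else "ok")
  })
  names(results) <- config$classifiers
  results
}

#' Run the full pipeline: data to cross-validated report
#'
#' Executes generate/ingest, preprocess, mask, extract, vocabulary,
#' encode and cross-validate, writing all artifacts under `outDir`:
#' `data/` (for synthetic runs), `descriptors.bin`, `vocabulary.bovw`,
#' `histograms.csv`, `report.json`, `report.csv` and `run_record.json`.
#' `report.json` contains no timestamps or absolute paths, so re-running
#' with an identical config and inputs reproduces it byte-identically;
#' timings and environment notes live in `run_record.json`.
#'
#' @param config a [pipelineConfig()].
#' @param manifest optional manifest data.frame ([readManifest()]); when
#'   `NULL` the config's `synthetic` block must be set and a dataset is
#'   generated under `outDir/data`.
#' @param outDir run directory (created).
#' @return Invisibly, a list with `report`, `results`, `log`,
#'   `runRecord` and `outDir`.
#' @export
runPipeline <- function(config, manifest = NULL, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  if (is.null(manifest)) {
    if (is.null(config$synthetic))
      stop("no manifest given and no synthetic block in the config")
    ds <- generateDataset(config$synthetic, file.path(outDir, "data"))
    manifest <- datasetManifest(ds)
    attr(manifest, "dir") <- datasetDir(ds)
    timings$generate <- tic() - t0
  }

  t0 <- tic()
  batch <- batchExtract(manifest, config$filterParams, config$roiSpec,
                        config$extractor, preprocess = config$useEdgeImage)
  timings$extract <- tic() - t0
  saveDescriptors(batch, file.path(outDir, "descriptors.bin"))
  pooled <- sum(batch$log$nKeypoints)
  if (pooled < config$vocabK)
    stop("vocabulary stage: only ", pooled, " pooled descriptors for K = ",
         config$vocabK, "; generate more images or use a smaller K")

  if (config$strictCv) {
    t0 <- tic()
    results <- .crossValidateStrict(batch, manifest$label, config)
    timings$cv_strict <- tic() - t0
    fold <- foldAssignment(results[[1]])
    confusion <- NULL
    vocab <- NULL
  } else {
    t0 <- tic()
    vocab <- buildVocabulary(batch$descriptors, config$vocabK,
                             seed = deriveSeed(config$globalSeed, "kmeans"),
                             method = batch$method)
    timings$vocabulary <- tic() - t0
    saveVocabulary(vocab, file.path(outDir, "vocabulary.bovw"))
    bset <- encodeBovwSet(batch, vocab, config$normalizeHistograms)
    utils::write.csv(bovwCounts(bset), file.path(outDir, "histograms.csv"))
    t0 <- tic()
    cv <- crossValidate(bset, classifiers = config$classifiers,
                        nFolds = config$nFolds, seed = config$globalSeed)
    timings$cv <- tic() - t0
    results <- cv$results
    fold <- cv$foldAssignment
    confusion <- lapply(cv$confusion, as.data.frame.matrix)
  }

  report <- list(
    config = .configSnapshot(config),
    n_images = nrow(manifest),
    zero_keypoint_images = batch$log$path[batch$log$nKeypoints == 0L],
    extraction_errors = batch$log$path[!is.na(batch$log$error)],
    vocabulary = if (is.null(vocab)) NULL else
      list(K = vocabK(vocab), d = vocabDim(vocab),
           inertia = vocabInertia(vocab)),
    fold_assignment = as.list(fold),
    classifiers = lapply(results, function(r)
      list(status = r@status, fold_accuracies = foldAccuracies(r),
           mean_accuracy = meanAccuracy(r), sd_accuracy = sdAccuracy(r))),
    confusion = confusion)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  tbl <- data.frame(
    classifier = names(results),
    meanAccuracy = vapply(results, meanAccuracy, numeric(1)),
    sdAccuracy = vapply(results, sdAccuracy, numeric(1)))
  tbl$accuracy <- sprintf("%.1f%%+/-%.1f%%", 100 * tbl$meanAccuracy,
                          100 * tbl$sdAccuracy)
  utils::write.csv(tbl, file.path(outDir, "report.csv"), row.names = FALSE)

  runRecord <- list(package_version = as.character(
                      utils::packageVersion("molarBoVW")),
                    r_version = R.version.string,
                    timestamp = format(Sys.time(), tz = "UTC"),
                    out_dir = normalizePath(outDir),
                    timings_seconds = timings,
                    warnings = list(
                      zero_keypoint_images = report$zero_keypoint_images,
                      extraction_errors = report$extraction_errors))
  jsonlite::write_json(runRecord, file.path(outDir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(report = report, results = results, log = batch$log,
                 runRecord = runRecord, outDir = outDir))
}
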