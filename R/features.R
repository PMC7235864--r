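# descriptor dimensionality is fixed per method
descriptorDim <- function(method) {
  switch(method, ORB = 32L, SIFT = 128L, SURF = 64L, NA_integer_)
}

#' List the feature-extraction methods available in this build
#'
#' ORB and SIFT are provided through the scikit-image backend. SURF has
#' no implementation in the available backends (it is patent-encumbered
#' in common open-source stacks), so requesting it raises an explicit
#' capability error rather than silently substituting another method.
#'
#' @return Character vector of usable method names.
#' @export
availableFeatureMethods <- function() c("ORB", "SIFT")

#' Configure a keypoint/descriptor extractor
#'
#' @param method one of `ORB`, `SIFT`, `SURF` (descriptor dimensions 32,
#'   128 and 64 respectively; see [availableFeatureMethods()]).
#' @param maxKeypoints per-image cap; keypoints are kept by descending
#'   detector response. Bounds vocabulary-building memory.
#' @param detectorParams method-specific settings. ORB: `downscale` and
#'   `n_scales` of the image pyramid, and `fast_threshold` (default 0.05
#'   here: the detector runs on sparse edge maps, where the stock 0.08
#'   leaves smooth-rimmed structures undetected).
#' @param seed integer, reserved for stochastic detectors (the provided
#'   backends are deterministic).
#' @return A validated list of class `ExtractorConfig`.
#' @export
extractorConfig <- function(method = "ORB", maxKeypoints = 500L,
                            detectorParams = NULL, seed = 0L) {
  if (!method %in% c("ORB", "SIFT", "SURF"))
    stop("unknown feature method '", method,
         "'; expected ORB, SIFT or SURF")
  if (is.null(detectorParams))
    detectorParams <- if (method == "ORB")
      list(fast_threshold = 0.05, n_scales = 4) else list()
  if (maxKeypoints < 1L) stop("maxKeypoints must be positive")
  structure(list(method = method, maxKeypoints = as.integer(maxKeypoints),
                 detectorParams = detectorParams, seed = as.integer(seed)),
            class = "ExtractorConfig")
}

.pkgEnv <- new.env(parent = emptyenv())

# locate a python interpreter with scikit-image; cached per session
.featureBackend <- function() {
  if (!is.null(.pkgEnv$python)) return(.pkgEnv$python)
  py <- Sys.getenv("MOLARBOVW_PYTHON", unset = Sys.which("python"))
  ok <- nzchar(py) &&
    !inherits(try(system2(py, c("-c", "'import skimage, numpy'"),
                          stdout = FALSE, stderr = FALSE), silent = TRUE),
              "try-error")
  if (!ok || !nzchar(py))
    stop("feature extraction backend unavailable: needs a python ",
         "interpreter with scikit-image on PATH (or MOLARBOVW_PYTHON)")
  .pkgEnv$python <- py
  py
}

.checkMethodAvailable <- function(method) {
  if (!method %in% availableFeatureMethods())
    stop("feature method '", method, "' is not available in this build; ",
         "available: ", paste(availableFeatureMethods(), collapse = ", "))
}

# headerless column-major uint8 dump, the worker's wire format
.writeU8 <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(img), con)
  list(path = path, h = nrow(img), w = ncol(img))
}

# run the extraction worker over a set of image entries sharing one mask
.runExtractor <- function(imageEntries, maskEntry, config) {
  .checkMethodAvailable(config$method)
  out <- tempfile("extract_")
  dir.create(out)
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  job <- list(method = config$method,
              max_keypoints = config$maxKeypoints,
              detector_params = config$detectorParams,
              images = imageEntries,
              mask = maskEntry,
              out_dir = out)
  jobPath <- file.path(out, "job.json")
  jsonlite::write_json(job, jobPath, auto_unbox = TRUE, null = "null",
                       digits = NA)
  script <- system.file("python", "extract_keypoints.py",
                        package = "molarBoVW", mustWork = TRUE)
  status <- system2(.featureBackend(), c(script, jobPath),
                    stdout = file.path(out, "log.txt"),
                    stderr = file.path(out, "log.txt"))
  if (status != 0L)
    stop("feature extraction backend failed:\n",
         paste(readLines(file.path(out, "log.txt"), warn = FALSE),
               collapse = "\n"))
  res <- jsonlite::read_json(file.path(out, "result.json"),
                             simplifyVector = FALSE)
  d <- res$d
  ns <- vapply(res$images, function(e) as.integer(e$n), integer(1))
  errs <- vapply(res$images, function(e)
    if (is.null(e$error)) NA_character_ else e$error, character(1))
  total <- sum(ns)
  kpRaw <- readBin(file.path(out, "kp.bin"), "double", n = total * 5L,
                   size = 8L, endian = "little")
  kpAll <- matrix(kpRaw, ncol = 5L, byrow = TRUE)
  descRaw <- readBin(file.path(out, "desc.bin"), "integer",
                     n = total * d, size = 1L, signed = FALSE)
  descAll <- matrix(descRaw, ncol = d, byrow = TRUE)
  offsets <- cumsum(c(0L, ns))
  results <- vector("list", length(imageEntries))
  for (i in seq_along(imageEntries)) {
    idx <- if (ns[i] > 0L) (offsets[i] + 1L):offsets[i + 1L] else integer(0)
    kp <- kpAll[idx, , drop = FALSE]
    results[[i]] <- list(
      keypoints = data.frame(row = kp[, 1] + 1, col = kp[, 2] + 1,
                             scale = kp[, 3], orientation = kp[, 4],
                             response = kp[, 5]),
      descriptors = descAll[idx, , drop = FALSE],
      error = errs[i])
  }
  list(results = results, d = d)
}

#' Extract keypoints and descriptors from one radiograph
#'
#' Detection is restricted to the ROI mask: the detector runs on the
#' mask's bounding box and any keypoint whose (rounded) position falls
#' outside the mask is discarded. At most `maxKeypoints` keypoints are
#' returned, kept by descending response. Deterministic given the config.
#'
#' @param img integer matrix of 8-bit intensities (typically the
#'   preprocessed edge image).
#' @param mask a [RoiMask-class] of the same shape, or `NULL` for the
#'   whole image.
#' @param config an [extractorConfig()].
#' @return A list with `keypoints` (data.frame: 1-based `row`, `col`,
#'   `scale`, `orientation` in degrees, `response`), `descriptors`
#'   (n x d integer matrix), `method` and `d`.
#' @export
extractFeatures <- function(img, mask = NULL, config = extractorConfig()) {
  checkRadiograph(img)
  maskEntry <- NULL
  tmp <- tempfile("img_", fileext = ".u8")
  on.exit(unlink(tmp), add = TRUE)
  entry <- .writeU8(asIntegerImage(img), tmp)
  if (!is.null(mask)) {
    if (!identical(dim(img), dim(mask@mask)))
      stop("image is ", paste(dim(img), collapse = "x"), " but mask is ",
           paste(dim(mask@mask), collapse = "x"))
    maskPath <- tempfile("mask_", fileext = ".u8")
    on.exit(unlink(maskPath), add = TRUE)
    maskEntry <- .writeU8(mask@mask * 1L, maskPath)
  }
  ex <- .runExtractor(list(entry), maskEntry, config)
  r <- ex$results[[1]]
  if (!is.na(r$error)) stop("feature extraction failed: ", r$error)
  list(keypoints = r$keypoints, descriptors = r$descriptors,
       method = config$method, d = ex$d)
}

#' Preprocess and extract features for every image in a manifest
#'
#' For each manifest entry: read the image, run the smoothing /
#' edge-detection chain, build the ROI mask for the image's dimensions,
#' and extract descriptors inside the mask. Images that yield zero
#' keypoints are flagged in the log but retained (their BoVW histogram
#' will be all-zero); unreadable images get a per-image error entry and
#' the run continues. The whole batch fails only if every image fails.
#'
#' @param manifest data.frame from [readManifest()] (or with `path`,
#'   `label`; relative paths resolve against `attr(manifest, "dir")`).
#' @param params a [filterParams()].
#' @param spec a [roiSpec()].
#' @param config an [extractorConfig()].
#' @param preprocess logical; set `FALSE` to extract from the raw
#'   (smoothed-only skipped) images instead of the edge image.
#' @return A list with `descriptors` (list of n_i x d matrices, manifest
#'   order), `keypoints` (list of data.frames), `log` (data.frame:
#'   `path`, `label`, `nKeypoints`, `error`), `method`, `d`.
#' @export
batchExtract <- function(manifest, params = filterParams(),
                         spec = roiSpec(), config = extractorConfig(),
                         preprocess = TRUE) {
  .checkMethodAvailable(config$method)
  base <- attr(manifest, "dir")
  paths <- manifest$path
  if (!is.null(base))
    paths <- ifelse(grepl("^(/|[A-Za-z]:)", paths), paths,
                    file.path(base, paths))
  n <- length(paths)
  tmpdir <- tempfile("batch_")
  dir.create(tmpdir)
  on.exit(unlink(tmpdir, recursive = TRUE), add = TRUE)
  prepEntries <- vector("list", n)
  readErr <- rep(NA_character_, n)
  dims <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    img <- tryCatch({
      x <- readRadiograph(paths[i])
      if (preprocess) x <- preprocessChain(x, params)
      x
    }, error = function(e) e)
    if (inherits(img, "error")) {
      readErr[i] <- conditionMessage(img)
      next
    }
    dims[i, ] <- dim(img)
    prepEntries[[i]] <- .writeU8(img, file.path(tmpdir,
                                                sprintf("prep_%05d.u8", i)))
  }
  if (all(!is.na(readErr)))
    stop("all images failed to load/preprocess; first error: ", readErr[1])

  descriptors <- vector("list", n)
  keypoints <- vector("list", n)
  d <- descriptorDim(config$method)
  # one worker invocation per distinct image size (mask is size-specific)
  okIdx <- which(is.na(readErr))
  groups <- split(okIdx, paste(dims[okIdx, 1], dims[okIdx, 2]))
  for (g in groups) {
    h <- dims[g[1], 1]; w <- dims[g[1], 2]
    mask <- makeRoiMask(h, w, spec)
    maskEntry <- .writeU8(mask@mask * 1L,
                          file.path(tmpdir, sprintf("mask_%dx%d.u8", h, w)))
    ex <- .runExtractor(prepEntries[g], maskEntry, config)
    d <- ex$d
    for (j in seq_along(g)) {
      r <- ex$results[[j]]
      if (!is.na(r$error)) {
        readErr[g[j]] <- r$error
      } else {
        descriptors[[g[j]]] <- r$descriptors
        keypoints[[g[j]]] <- r$keypoints
      }
    }
  }
  for (i in which(!is.na(readErr))) {
    descriptors[[i]] <- matrix(0L, 0, d)
    keypoints[[i]] <- data.frame(row = numeric(0), col = numeric(0),
                                 scale = numeric(0),
                                 orientation = numeric(0),
                                 response = numeric(0))
  }
  log <- data.frame(path = manifest$path, label = manifest$label,
                    nKeypoints = vapply(descriptors, nrow, integer(1)),
                    error = readErr, stringsAsFactors = FALSE)
  list(descriptors = descriptors, keypoints = keypoints, log = log,
       method = config$method, d = d)
}

#' Persist / reload a descriptor collection
#'
#' One container file per run: a single-line JSON header (format tag,
#' method, descriptor dimension, per-image counts, image ids, config)
#' followed by the concatenated row-major descriptor block as unsigned
#' bytes. The round-trip is bit-exact.
#'
#' @param x result of [batchExtract()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
saveDescriptors <- function(x, path) {
  header <- list(format = "molarBoVW-descriptors-v1", method = x$method,
                 d = x$d, counts = vapply(x$descriptors, nrow, integer(1)),
                 images = x$log$path, labels = x$log$label)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(jsonlite::toJSON(header, auto_unbox = TRUE),
                            "\n")), con)
  for (m in x$descriptors) {
    if (nrow(m)) writeBin(as.raw(t(m)), con)
  }
  invisible(path)
}

#' @rdname saveDescriptors
#' @export
loadDescriptors <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  nl <- which(bytes == as.raw(10L))[1]
  if (is.na(nl)) stop("corrupt descriptor file: missing header")
  header <- jsonlite::fromJSON(rawToChar(bytes[seq_len(nl - 1L)]))
  if (!identical(header$format, "molarBoVW-descriptors-v1"))
    stop("corrupt descriptor file: unrecognized header")
  counts <- as.integer(header$counts)
  d <- as.integer(header$d)
  block <- bytes[-seq_len(nl)]
  if (length(block) != sum(counts) * d)
    stop("corrupt descriptor file: expected ", sum(counts) * d,
         " descriptor bytes, found ", length(block))
  vals <- as.integer(block)
  offsets <- cumsum(c(0L, counts))
  descriptors <- lapply(seq_along(counts), function(i) {
    if (counts[i] == 0L) return(matrix(0L, 0, d))
    seg <- vals[(offsets[i] * d + 1L):(offsets[i + 1L] * d)]
    matrix(seg, ncol = d, byrow = TRUE)
  })
  list(descriptors = descriptors, method = header$method, d = d,
       log = data.frame(path = header$images, label = header$labels,
                        nKeypoints = counts, error = NA_character_,
                        stringsAsFactors = FALSE))
}
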