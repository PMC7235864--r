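#' Class labels used throughout the package
#'
#' The three complication groups a panoramic radiograph is assigned to:
#' `R8_Lower` (lower third molars affected), `R8_Null` (no complication),
#' `R8_Upper_Lower` (upper and lower third molars affected).
#'
#' @export
MOLAR_CLASSES <- c("R8_Lower", "R8_Null", "R8_Upper_Lower")

#' RoiSpec: fixed-coordinate third-molar region of interest
#'
#' Half-open index ranges `[rowStart, rowEnd) x [colStart, colEnd)` on a
#' reference image size. On images of other dimensions the ranges are
#' rescaled proportionally (see [makeRoiMask()]). Defaults are the band in
#' which third molars sit on a 1200 x 2400 panoramic radiograph: rows
#' 300-900, columns 490-2200.
#'
#' @slot rowStart,rowEnd,colStart,colEnd integer 0-based half-open bounds.
#' @slot refHeight,refWidth integer reference image dimensions.
#' @export
setClass("RoiSpec", representation(
  rowStart = "integer", rowEnd = "integer",
  colStart = "integer", colEnd = "integer",
  refHeight = "integer", refWidth = "integer"
), validity = function(object) {
  if (object@rowStart < 0L || object@rowStart >= object@rowEnd)
    return("need 0 <= rowStart < rowEnd")
  if (object@colStart < 0L || object@colStart >= object@colEnd)
    return("need 0 <= colStart < colEnd")
  if (object@refHeight < 1L || object@refWidth < 1L)
    return("reference dimensions must be positive")
  TRUE
})

#' RoiMask: binary inclusion mask over an image
#'
#' Marks the pixels examined for features; the image is never cropped,
#' pixels outside the mask are simply ignored (or zeroed by [applyMask()]).
#'
#' @slot mask logical matrix, same shape as the target image.
#' @slot includedPixelCount integer number of `TRUE` entries.
#' @export
setClass("RoiMask", representation(
  mask = "matrix", includedPixelCount = "integer"
), validity = function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (sum(object@mask) != object@includedPixelCount)
    return("includedPixelCount does not match the mask")
  TRUE
})

#' SyntheticConfig: parameters of the phantom radiograph generator
#'
#' @slot nImages integer number of images (>= 3).
#' @slot classProportions numeric length-3, nonnegative, summing to 1, in
#'   the order `R8_Lower`, `R8_Null`, `R8_Upper_Lower`.
#' @slot height,width integer image dimensions in pixels. Must be at least
#'   901 x 2201 so the canonical ROI coordinates apply unscaled.
#' @slot noiseSigma numeric Gaussian mottle standard deviation (gray levels).
#' @slot mottlePoisson logical, apply Poisson (variance-proportional-to-
#'   intensity) mottle before the Gaussian component.
#' @slot molarContrast numeric peak contrast of molar structures (gray levels).
#' @slot tiltRange numeric maximum absolute tilt of affected molars (degrees).
#' @slot seed integer generator seed.
#' @export
setClass("SyntheticConfig", representation(
  nImages = "integer", classProportions = "numeric",
  height = "integer", width = "integer",
  noiseSigma = "numeric", mottlePoisson = "logical",
  molarContrast = "numeric", tiltRange = "numeric", seed = "integer"
), validity = function(object) {
  p <- object@classProportions
  if (length(p) != 3L || any(p < 0)) {
    return("classProportions must be 3 nonnegative fractions")
  }
  if (abs(sum(p) - 1) > 1e-9) return("classProportions must sum to 1")
  if (object@nImages < 3L) return("nImages must be >= 3")
  if (object@height < 901L || object@width < 2201L)
    return(sprintf(
      "dimensions %dx%d too small for the unscaled ROI; minimum is 901x2201",
      object@height, object@width))
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@tiltRange < 0) return("tiltRange must be >= 0")
  TRUE
})

#' SyntheticDataset: an on-disk labelled phantom dataset
#'
#' @slot manifest data.frame with columns `path` (relative to `dir`) and
#'   `label`.
#' @slot sites data.frame of ground-truth molar sites, one row per site per
#'   image: `image`, `site`, `row`, `col`, `tilt`, `present`.
#' @slot config the [SyntheticConfig-class] that produced it.
#' @slot dir character directory holding the PNG images and manifest.
#' @export
setClass("SyntheticDataset", representation(
  manifest = "data.frame", sites = "data.frame",
  config = "SyntheticConfig", dir = "character"
))

#' Vocabulary: a K-means visual codebook
#'
#' The K cluster centers over descriptor space; each image histogram counts
#' how many of its descriptors fall nearest to each center.
#'
#' @slot centers K x d numeric matrix of cluster centers.
#' @slot method extractor name the centers were built from (`ORB`/`SIFT`).
#' @slot kmeansSeed integer seed used for k-means++ initialisation.
#' @slot inertia numeric sum of squared distances at convergence.
#' @slot inertiaHistory numeric per-assignment-step inertia trace.
#' @export
setClass("Vocabulary", representation(
  centers = "matrix", method = "character", kmeansSeed = "integer",
  inertia = "numeric", inertiaHistory = "numeric"
), validity = function(object) {
  if (nrow(object@centers) < 1L) return("need K >= 1 centers")
  if (!all(is.finite(object@centers))) return("centers must be finite")
  d <- descriptorDim(object@method)
  if (!is.na(d) && ncol(object@centers) != d)
    return(sprintf("method %s implies descriptor dimension %d, centers have %d",
                   object@method, d, ncol(object@centers)))
  TRUE
})

#' BovwSet: bag-of-visual-words histograms for a set of images
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single `counts`
#' assay is the K x n visual-word histogram matrix (words in rows, images
#' in columns), with image labels in `colData` and the vocabulary metadata
#' in `metadata()`.
#'
#' @export
setClass("BovwSet", contains = "SummarizedExperiment",
  validity = function(object) {
    a <- SummarizedExperiment::assay(object, "counts")
    if (any(a < 0)) return("histogram entries must be nonnegative")
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
      return("colData must contain a 'label' column")
    TRUE
  })

#' CvResult: one classifier's k-fold cross-validation outcome
#'
#' @slot classifier classifier name.
#' @slot foldAccuracies numeric per-fold validation accuracies in `[0, 1]`.
#' @slot meanAccuracy arithmetic mean of the fold accuracies.
#' @slot sdAccuracy population standard deviation of the fold accuracies.
#' @slot foldAssignment integer fold index per image, named by image id.
#' @slot seed integer seed of the run.
#' @slot status `"ok"` or `"failed"` (training failed in some fold).
#' @export
setClass("CvResult", representation(
  classifier = "character", foldAccuracies = "numeric",
  meanAccuracy = "numeric", sdAccuracy = "numeric",
  foldAssignment = "integer", seed = "integer", status = "character"
), validity = function(object) {
  ok <- object@foldAccuracies[!is.na(object@foldAccuracies)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 1))
    return("fold accuracies must lie in [0, 1]")
  if (length(ok) &&
      abs(object@meanAccuracy - mean(ok)) > 1e-12)
    return("meanAccuracy must equal the mean of the fold accuracies")
  TRUE
})

#' BovwModel: a fitted classifier over BoVW histograms
#'
#' @slot name classifier name, one of [classifierNames()].
#' @slot fit the underlying fitted model object.
#' @slot levels class labels seen at training.
#' @slot dim integer histogram length (K) the model expects.
#' @slot method extractor method the training histograms came from, or `NA`.
#' @slot seed integer training seed.
#' @export
setClass("BovwModel", representation(
  name = "character", fit = "ANY", levels = "character",
  dim = "integer", method = "character", seed = "integer"
))

setMethod("show", "RoiSpec", function(object) {
  cat(sprintf("RoiSpec rows [%d, %d) x cols [%d, %d) on %d x %d reference\n",
              object@rowStart, object@rowEnd, object@colStart, object@colEnd,
              object@refHeight, object@refWidth))
})

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask %d x %d, %d pixels included (%.1f%%)\n",
              nrow(object@mask), ncol(object@mask), object@includedPixelCount,
              100 * object@includedPixelCount / length(object@mask)))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d images (%d x %d) in %s\n",
              nrow(object@manifest), object@config@height,
              object@config@width, object@dir))
  print(table(object@manifest$label))
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: K = %d visual words, d = %d (%s), inertia %.4g\n",
              nrow(object@centers), ncol(object@centers), object@method,
              object@inertia))
})

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult [%s] %s: accuracy %.3f +/- %.3f over %d folds\n",
              object@status, object@classifier, object@meanAccuracy,
              object@sdAccuracy, length(object@foldAccuracies)))
})

setMethod("show", "BovwModel", function(object) {
  cat(sprintf("BovwModel: %s over %d-bin histograms (%s), classes: %s\n",
              object@name, object@dim,
              ifelse(is.na(object@method), "method unset", object@method),
              paste(object@levels, collapse = ", ")))
})
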