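#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `vocabCenters()`, `vocabMethod()`, `vocabK()`, `vocabDim()`,
#' `vocabInertia()` for [Vocabulary-class]; `roiMask()`,
#' `includedPixels()` for [RoiMask-class]; `bovwLabels()`, `bovwCounts()`
#' for [BovwSet-class]; `foldAccuracies()`, `meanAccuracy()`,
#' `sdAccuracy()`, `foldAssignment()` for [CvResult-class];
#' `datasetManifest()`, `datasetSites()`, `datasetDir()` for
#' [SyntheticDataset-class].
#'
#' @param x an object of the matching class.
#' @return The slot value (matrix, vector or data.frame as documented).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vocabCenters", function(x) standardGeneric("vocabCenters"))
#' @rdname accessors
#' @export
setGeneric("vocabMethod", function(x) standardGeneric("vocabMethod"))
#' @rdname accessors
#' @export
setGeneric("vocabK", function(x) standardGeneric("vocabK"))
#' @rdname accessors
#' @export
setGeneric("vocabDim", function(x) standardGeneric("vocabDim"))
#' @rdname accessors
#' @export
setGeneric("vocabInertia", function(x) standardGeneric("vocabInertia"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("includedPixels", function(x) standardGeneric("includedPixels"))
#' @rdname accessors
#' @export
setGeneric("bovwLabels", function(x) standardGeneric("bovwLabels"))
#' @rdname accessors
#' @export
setGeneric("bovwCounts", function(x) standardGeneric("bovwCounts"))
#' @rdname accessors
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))
#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
#' @rdname accessors
#' @export
setGeneric("sdAccuracy", function(x) standardGeneric("sdAccuracy"))
#' @rdname accessors
#' @export
setGeneric("foldAssignment", function(x) standardGeneric("foldAssignment"))
#' @rdname accessors
#' @export
setGeneric("datasetManifest", function(x) standardGeneric("datasetManifest"))
#' @rdname accessors
#' @export
setGeneric("datasetSites", function(x) standardGeneric("datasetSites"))
#' @rdname accessors
#' @export
setGeneric("datasetDir", function(x) standardGeneric("datasetDir"))

#' @rdname accessors
setMethod("vocabCenters", "Vocabulary", function(x) x@centers)
#' @rdname accessors
setMethod("vocabMethod", "Vocabulary", function(x) x@method)
#' @rdname accessors
setMethod("vocabK", "Vocabulary", function(x) nrow(x@centers))
#' @rdname accessors
setMethod("vocabDim", "Vocabulary", function(x) ncol(x@centers))
#' @rdname accessors
setMethod("vocabInertia", "Vocabulary", function(x) x@inertia)
#' @rdname accessors
setMethod("roiMask", "RoiMask", function(x) x@mask)
#' @rdname accessors
setMethod("includedPixels", "RoiMask", function(x) x@includedPixelCount)
#' @rdname accessors
setMethod("bovwLabels", "BovwSet", function(x)
  as.character(SummarizedExperiment::colData(x)$label))
#' @rdname accessors
setMethod("bovwCounts", "BovwSet", function(x)
  SummarizedExperiment::assay(x, "counts"))
#' @rdname accessors
setMethod("foldAccuracies", "CvResult", function(x) x@foldAccuracies)
#' @rdname accessors
setMethod("meanAccuracy", "CvResult", function(x) x@meanAccuracy)
#' @rdname accessors
setMethod("sdAccuracy", "CvResult", function(x) x@sdAccuracy)
#' @rdname accessors
setMethod("foldAssignment", "CvResult", function(x) x@foldAssignment)
#' @rdname accessors
setMethod("datasetManifest", "SyntheticDataset", function(x) x@manifest)
#' @rdname accessors
setMethod("datasetSites", "SyntheticDataset", function(x) x@sites)
#' @rdname accessors
setMethod("datasetDir", "SyntheticDataset", function(x) x@dir)
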