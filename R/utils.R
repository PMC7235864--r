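#' @useDynLib molarBoVW, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats predict
NULL

# Half-up rounding at every 8-bit conversion; base round() rounds half to
# even, which would break the exact filter oracles.
roundHalfUp <- function(x) floor(x + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

#' Derive a stage seed from the global seed
#'
#' All randomness in a run descends from one global seed. Each pipeline
#' stage draws its own seed as `(hash(stage) + seed * 10007) mod (2^31 - 1)`
#' where `hash` is a base-31 polynomial over the stage name's UTF-8 bytes,
#' so one integer reproduces a whole run while stages stay decorrelated.
#'
#' @param seed integer global seed.
#' @param stage character stage name, e.g. `"kmeans"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((h + (seed %% m) * 10007) %% m)
}

# asserts an image is an integer-valued matrix in [0, 255]
checkRadiograph <- function(img, minDim = 1L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("radiograph must be a numeric matrix of 8-bit intensities")
  if (nrow(img) < minDim || ncol(img) < minDim)
    stop(sprintf("image must be at least %dx%d, got %dx%d",
                 minDim, minDim, nrow(img), ncol(img)))
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("pixel values must lie in [0, 255]")
  invisible(img)
}

asIntegerImage <- function(img) {
  storage.mode(img) <- "integer"
  img
}
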