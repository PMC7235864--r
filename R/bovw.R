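#' Build a K-means visual vocabulary from pooled descriptors
#'
#' Runs Lloyd's algorithm with k-means++ initialisation over all pooled
#' descriptor rows. Binary descriptors (ORB bytes) are cast to real
#' vectors and clustered with Euclidean distance, matching the uniform
#' treatment of all extractor types. Convergence when the largest center
#' shift drops below `tol` or after `maxIter` iterations; empty clusters
#' are re-seeded from the point farthest from its assigned center.
#' Deterministic given `seed`.
#'
#' @param descriptors an n x d numeric matrix, or a list of per-image
#'   matrices (as from [batchExtract()]) which are pooled by row.
#' @param K number of visual words (published recipe: 2800; for
#'   desk-scale synthetic runs 200 is the preset).
#' @param seed integer seed for the k-means++ draws.
#' @param method extractor name recorded in the vocabulary (`ORB`,
#'   `SIFT`, `SURF` or `""` for untyped descriptor spaces).
#' @param maxIter,tol Lloyd iteration cap and center-shift tolerance.
#' @return A [Vocabulary-class].
#' @export
buildVocabulary <- function(descriptors, K, seed = 0L, method = "",
                            maxIter = 300L, tol = 1e-4) {
  if (is.list(descriptors)) {
    descriptors <- descriptors[vapply(descriptors, nrow, integer(1)) > 0]
    descriptors <- do.call(rbind, descriptors)
  }
  X <- matrix(as.numeric(descriptors), nrow = nrow(descriptors))
  if (anyNA(X) || !all(is.finite(X))) stop("descriptors must be finite")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (nrow(X) < K)
    stop("only ", nrow(X), " pooled descriptors for K = ", K,
         " clusters; use a smaller K (the synthetic preset uses K = 200)")
  set.seed(as.integer(seed %% 2147483647))
  fit <- .lloyd_kmeans_cpp(X, K, as.integer(maxIter), tol)
  new("Vocabulary", centers = fit$centers, method = method,
      kmeansSeed = as.integer(seed), inertia = fit$inertia,
      inertiaHistory = fit$inertia_history)
}

#' Encode descriptors as a visual-word histogram
#'
#' Each descriptor is assigned to its Euclidean-nearest vocabulary
#' center (ties break to the lowest center index) and the per-word
#' counts are accumulated. With `normalize = TRUE` the counts are L1
#' normalised so images with different keypoint counts are comparable;
#' a zero-descriptor input yields an all-zero histogram with the
#' normalized flag forced off.
#'
#' @param descriptors n x d matrix (possibly 0-row).
#' @param vocab a [Vocabulary-class].
#' @param normalize L1-normalise the histogram.
#' @return Numeric length-K vector with attributes `nDescriptors` and
#'   `normalized`.
#' @export
encodeBovw <- function(descriptors, vocab, normalize = TRUE) {
  K <- vocabK(vocab)
  d <- vocabDim(vocab)
  if (nrow(descriptors) == 0L) {
    h <- numeric(K)
    attr(h, "nDescriptors") <- 0L
    attr(h, "normalized") <- FALSE
    return(h)
  }
  if (ncol(descriptors) != d)
    stop("descriptor dimension ", ncol(descriptors),
         " does not match vocabulary dimension ", d)
  X <- matrix(as.numeric(descriptors), nrow = nrow(descriptors))
  idx <- .assign_nearest_cpp(X, vocab@centers)
  h <- as.numeric(tabulate(idx, nbins = K))
  n <- nrow(descriptors)
  if (normalize) h <- h / n
  attr(h, "nDescriptors") <- n
  attr(h, "normalized") <- isTRUE(normalize)
  h
}

#' Encode a whole descriptor collection as a BovwSet
#'
#' @param batch result of [batchExtract()] or [loadDescriptors()].
#' @param vocab a [Vocabulary-class]; its method must match the batch's.
#' @param normalize L1-normalise each histogram.
#' @return A [BovwSet-class] (words x images).
#' @export
encodeBovwSet <- function(batch, vocab, normalize = TRUE) {
  if (nzchar(vocab@method) && nzchar(batch$method) &&
      !identical(vocab@method, batch$method))
    stop("vocabulary was built from ", vocab@method,
         " descriptors but the batch is ", batch$method)
  H <- vapply(batch$descriptors, function(m)
    as.numeric(encodeBovw(m, vocab, normalize)), numeric(vocabK(vocab)))
  if (is.null(dim(H))) H <- matrix(H, nrow = vocabK(vocab))
  ids <- make.unique(basename(batch$log$path))
  colnames(H) <- ids
  rownames(H) <- paste0("w", seq_len(vocabK(vocab)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = H),
    colData = S4Vectors::DataFrame(label = batch$log$label,
                                   imageId = ids,
                                   nKeypoints = batch$log$nKeypoints,
                                   row.names = ids),
    metadata = list(method = batch$method, normalized = isTRUE(normalize),
                    K = vocabK(vocab), kmeansSeed = vocab@kmeansSeed))
  new("BovwSet", se)
}

#' Save / load a visual vocabulary (`.bovw` file)
#'
#' Portable container: a single-line JSON header (format tag, K, d,
#' method, seed, inertia, byte order) followed by the row-major
#' little-endian float64 block of cluster centers. The round-trip is
#' bit-exact; a truncated or oversized block is a corruption error, not
#' a partial vocabulary.
#'
#' @param vocab a [Vocabulary-class].
#' @param path file path (conventionally `.bovw`).
#' @return `saveVocabulary`: invisibly, `path`; `loadVocabulary`: the
#'   reloaded [Vocabulary-class].
#' @export
saveVocabulary <- function(vocab, path) {
  header <- list(format = "molarBoVW-vocabulary-v1",
                 K = vocabK(vocab), d = vocabDim(vocab),
                 method = vocab@method, kmeans_seed = vocab@kmeansSeed,
                 inertia = vocab@inertia, byte_order = "little")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(jsonlite::toJSON(header, auto_unbox = TRUE,
                                             digits = NA), "\n")), con)
  writeBin(as.numeric(t(vocab@centers)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname saveVocabulary
#' @export
loadVocabulary <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  nl <- which(bytes == as.raw(10L))[1]
  if (is.na(nl)) stop("corrupt vocabulary file: missing header")
  header <- tryCatch(jsonlite::fromJSON(rawToChar(bytes[seq_len(nl - 1L)])),
                     error = function(e) NULL)
  if (is.null(header) ||
      !identical(header$format, "molarBoVW-vocabulary-v1"))
    stop("corrupt vocabulary file: unrecognized header")
  K <- as.integer(header$K); d <- as.integer(header$d)
  block <- bytes[-seq_len(nl)]
  if (length(block) != K * d * 8L)
    stop("corrupt vocabulary file: expected ", K * d * 8L,
         " center bytes, found ", length(block))
  centers <- matrix(readBin(block, "double", n = K * d, size = 8L,
                            endian = "little"),
                    nrow = K, ncol = d, byrow = TRUE)
  new("Vocabulary", centers = centers, method = header$method,
      kmeansSeed = as.integer(header$kmeans_seed),
      inertia = as.numeric(header$inertia),
      inertiaHistory = numeric(0))
}
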