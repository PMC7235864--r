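#' Smoothing and edge-detection parameters
#'
#' Defaults are the published pipeline settings: a 3x3 median filter
#' against quantum mottle, a bilateral filter of diameter 9 with
#' sigmaColor = sigmaSpace = 75, and an equal-weight blend of the absolute
#' Sobel X and Y gradients.
#'
#' @param medianKernel odd kernel size in pixels (>= 3).
#' @param bilateralDiameter odd window diameter in pixels (>= 3).
#' @param sigmaColor Gaussian width over intensity differences (gray levels).
#' @param sigmaSpace Gaussian width over pixel distance (pixels).
#' @param blendWx,blendWy nonnegative blend weights for |gx| and |gy|.
#' @return A validated list of class `FilterParams`.
#' @export
filterParams <- function(medianKernel = 3L, bilateralDiameter = 9L,
                         sigmaColor = 75, sigmaSpace = 75,
                         blendWx = 0.5, blendWy = 0.5) {
  medianKernel <- as.integer(medianKernel)
  bilateralDiameter <- as.integer(bilateralDiameter)
  if (medianKernel < 3L || medianKernel %% 2L == 0L)
    stop("medianKernel must be odd and >= 3")
  if (bilateralDiameter < 3L || bilateralDiameter %% 2L == 0L)
    stop("bilateralDiameter must be odd and >= 3")
  if (sigmaColor <= 0 || sigmaSpace <= 0) stop("sigmas must be > 0")
  if (blendWx < 0 || blendWy < 0) stop("blend weights must be >= 0")
  structure(list(medianKernel = medianKernel,
                 bilateralDiameter = bilateralDiameter,
                 sigmaColor = sigmaColor, sigmaSpace = sigmaSpace,
                 blendWx = blendWx, blendWy = blendWy),
            class = "FilterParams")
}

#' Median filter with reflect-101 borders
#'
#' Each output pixel is the median of its `kernel x kernel` neighborhood;
#' borders are mirrored about the edge pixel (reflect-101), which avoids
#' the dark frame artifacts that zero padding would put under the edge
#' detector.
#'
#' @param img integer matrix of 8-bit intensities.
#' @param kernel odd kernel size (default 3).
#' @return Filtered integer matrix, same shape.
#' @export
medianSmooth <- function(img, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L || kernel < 3L) stop("kernel must be odd and >= 3")
  checkRadiograph(img, minDim = 3L)
  if (kernel > min(dim(img)))
    stop("kernel exceeds the smallest image dimension")
  .median_filter_cpp(asIntegerImage(img), kernel)
}

#' Bilateral filter (edge-preserving smoothing)
#'
#' `out(p) = sum_q I(q) ws(|p-q|) wc(|I(q)-I(p)|) / sum_q ws wc` over the
#' `diameter x diameter` window around `p`, with Gaussian spatial and
#' intensity kernels, reflect-101 borders and half-up rounding back to
#' 8 bits.
#'
#' @param img integer matrix of 8-bit intensities.
#' @param params a [filterParams()] list (uses `bilateralDiameter`,
#'   `sigmaColor`, `sigmaSpace`).
#' @return Filtered integer matrix, same shape.
#' @export
bilateralSmooth <- function(img, params = filterParams()) {
  checkRadiograph(img, minDim = 3L)
  .bilateral_filter_cpp(asIntegerImage(img), params$bilateralDiameter,
                        params$sigmaColor, params$sigmaSpace)
}

#' Sobel X and Y gradients
#'
#' Cross-correlation with `[[-1,0,1],[-2,0,2],[-1,0,1]]` for the X
#' (column) gradient and its transpose for Y, reflect-101 borders. The
#' output is signed and not clipped.
#'
#' @param img integer matrix of 8-bit intensities, at least 3x3.
#' @return A list with integer matrices `gx` and `gy`.
#' @export
sobelGradients <- function(img) {
  checkRadiograph(img, minDim = 3L)
  .sobel_cpp(asIntegerImage(img))
}

#' Blend signed gradients into one 8-bit edge image
#'
#' Each gradient is mapped to its absolute value and clipped to
#' `[0, 255]` ("converted back to uint8"), then the two are combined as
#' `round(wx * |gx| + wy * |gy|)`, clipped again.
#'
#' @param grads list with `gx` and `gy` matrices of identical shape.
#' @param params a [filterParams()] list (uses `blendWx`, `blendWy`).
#' @return Integer matrix of 8-bit edge intensities.
#' @export
blendGradients <- function(grads, params = filterParams()) {
  gx <- grads$gx; gy <- grads$gy
  if (!identical(dim(gx), dim(gy)))
    stop("gradient shapes differ: ", paste(dim(gx), collapse = "x"), " vs ",
         paste(dim(gy), collapse = "x"))
  .blend_cpp(asIntegerImage(gx), asIntegerImage(gy),
             params$blendWx, params$blendWy)
}

#' Full smoothing and edge-detection chain
#'
#' Median filter, then bilateral filter, then Sobel gradients, then the
#' uint8 gradient blend — the four preprocessing steps applied to every
#' radiograph before feature extraction. Deterministic.
#'
#' @param img integer matrix of 8-bit intensities.
#' @param params a [filterParams()] list.
#' @return Integer matrix: the blended edge image.
#' @export
preprocessChain <- function(img, params = filterParams()) {
  x <- medianSmooth(img, params$medianKernel)
  x <- bilateralSmooth(x, params)
  blendGradients(sobelGradients(x), params)
}
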