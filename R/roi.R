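#' Construct a third-molar ROI specification
#'
#' The default band `rows [300, 900) x cols [490, 2200)` on a 1200 x 2400
#' reference image covers all four third-molar sites of a typical
#' panoramic radiograph; the ranges follow slice (half-open) convention.
#'
#' @param rowStart,rowEnd,colStart,colEnd 0-based half-open pixel bounds.
#' @param refHeight,refWidth reference image dimensions the bounds refer to.
#' @return A [RoiSpec-class] object.
#' @export
roiSpec <- function(rowStart = 300L, rowEnd = 900L,
                    colStart = 490L, colEnd = 2200L,
                    refHeight = 1200L, refWidth = 2400L) {
  new("RoiSpec",
      rowStart = as.integer(rowStart), rowEnd = as.integer(rowEnd),
      colStart = as.integer(colStart), colEnd = as.integer(colEnd),
      refHeight = as.integer(refHeight), refWidth = as.integer(refWidth))
}

#' Build the binary ROI mask for an image size
#'
#' Sets the half-open ranges `[rowStart, rowEnd) x [colStart, colEnd)` to
#' `TRUE`. If the target size differs from the `RoiSpec`'s reference size the
#' bounds are rescaled proportionally and rounded half-up, since the ROI
#' coordinates are only valid relative to the image dimension.
#'
#' @param height,width target image dimensions in pixels.
#' @param spec a [roiSpec()].
#' @return A [RoiMask-class].
#' @export
makeRoiMask <- function(height, width, spec = roiSpec()) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) stop("height and width must be positive")
  rs <- spec@rowStart; re <- spec@rowEnd
  cs <- spec@colStart; ce <- spec@colEnd
  if (height != spec@refHeight) {
    f <- height / spec@refHeight
    rs <- roundHalfUp(rs * f); re <- roundHalfUp(re * f)
  }
  if (width != spec@refWidth) {
    f <- width / spec@refWidth
    cs <- roundHalfUp(cs * f); ce <- roundHalfUp(ce * f)
  }
  re <- min(re, height); ce <- min(ce, width)
  if (rs >= re || cs >= ce)
    stop(sprintf("rescaled ROI [%d,%d)x[%d,%d) is empty for a %dx%d image",
                 rs, re, cs, ce, height, width))
  m <- matrix(FALSE, height, width)
  m[(rs + 1L):re, (cs + 1L):ce] <- TRUE  # 0-based half-open -> 1-based closed
  new("RoiMask", mask = m, includedPixelCount = as.integer((re - rs) * (ce - cs)))
}

#' Zero out all pixels outside the ROI
#'
#' The mask specifies which region to examine; dimensions are unchanged
#' (masking, not cropping). Idempotent.
#'
#' @param img integer matrix of 8-bit intensities.
#' @param mask a [RoiMask-class] of the same shape.
#' @return Integer matrix with out-of-ROI pixels set to 0.
#' @export
applyMask <- function(img, mask) {
  if (!identical(dim(img), dim(mask@mask)))
    stop("image is ", paste(dim(img), collapse = "x"), " but mask is ",
         paste(dim(mask@mask), collapse = "x"))
  out <- img
  out[!mask@mask] <- 0L
  asIntegerImage(out)
}

#' Write a mask-overlay preview PNG for visual audit
#'
#' The image is rendered in gray with the ROI tinted green, so users can
#' verify on their own data that the row/column convention matches the
#' anatomy before running feature extraction.
#'
#' @param img integer matrix of 8-bit intensities.
#' @param mask a [RoiMask-class] of the same shape.
#' @param path output PNG path.
#' @return Invisibly, the number of highlighted pixels.
#' @export
roiPreview <- function(img, mask, path) {
  if (!identical(dim(img), dim(mask@mask)))
    stop("image/mask shape mismatch")
  g <- img / 255
  rgb <- array(g, dim = c(dim(img), 3L))
  sel <- mask@mask
  rgb[, , 2][sel] <- pmin(rgb[, , 2][sel] * 0.6 + 0.4, 1)
  rgb[, , 1][sel] <- rgb[, , 1][sel] * 0.6
  rgb[, , 3][sel] <- rgb[, , 3][sel] * 0.6
  png::writePNG(rgb, path)
  invisible(mask@includedPixelCount)
}
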