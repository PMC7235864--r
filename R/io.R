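#' Convert a possibly multi-channel image to an 8-bit grayscale radiograph
#'
#' Three-channel input is converted with the fixed luma weights
#' (0.299, 0.587, 0.114), rounded half-up and clipped to `[0, 255]`;
#' single-channel input passes through unchanged. Any other channel count
#' is a format error (alpha channels must be dropped upstream).
#'
#' @param img an `h x w` numeric matrix (already gray) or `h x w x 3` array
#'   of 8-bit intensities.
#' @return An integer matrix of 8-bit intensities.
#' @export
toGrayscale <- function(img) {
  if (is.matrix(img)) {
    checkRadiograph(img)
    return(asIntegerImage(img))
  }
  if (is.array(img) && length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 1L) {
      g <- img[, , 1]
      dim(g) <- dim(img)[1:2]
      return(asIntegerImage(g))
    }
    if (nc != 3L)
      stop(sprintf("unsupported channel count %d: expected 1 or 3", nc))
    g <- clip8(roundHalfUp(0.299 * img[, , 1] + 0.587 * img[, , 2] +
                             0.114 * img[, , 3]))
    dim(g) <- dim(img)[1:2]
    return(asIntegerImage(g))
  }
  stop("unsupported image format: expected a matrix or h x w x c array")
}

#' Read a radiograph from a PNG or TIFF file
#'
#' Pixels are scaled to 8-bit intensities and multi-channel images are
#' collapsed to grayscale with [toGrayscale()]. An alpha channel, if
#' present and fully opaque, is dropped.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @return An integer matrix of 8-bit intensities.
#' @export
readRadiograph <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format '", ext, "': expected png or tiff")
  }
  x <- roundHalfUp(raw * 255)
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] %in% c(2L, 4L)) {
    alpha <- x[, , dim(x)[3]]
    if (any(alpha < 255)) stop("images with transparency are not supported")
    x <- x[, , -dim(x)[3], drop = FALSE]
    if (dim(x)[3] == 1L) x <- x[, , 1]
  }
  toGrayscale(x)
}

#' Write a radiograph as an 8-bit single-channel PNG
#'
#' @param img integer matrix of 8-bit intensities.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeRadiograph <- function(img, path) {
  checkRadiograph(img)
  png::writePNG(img / 255, path)
  invisible(path)
}
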