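#' Configure the synthetic panoramic-radiograph generator
#'
#' The generator emulates the statistical structure the pipeline relies
#' on: smooth low-frequency anatomy, a jaw-arch band, four third-molar
#' sites inside the canonical ROI band, class-dependent textured and
#' tilted molar structure, and quantum-mottle-style noise (Poisson
#' variance-proportional-to-intensity mottle followed by additive
#' Gaussian noise). Because bag-of-visual-words histograms discard
#' keypoint positions, the class signal is carried by local texture:
#' affected lower molars are rendered with a checkerboard pattern and
#' affected upper molars with a bright dot lattice, two structurally
#' distinct local textures whose keypoint descriptors quantise into
#' different visual words.
#'
#' @param nImages number of images (>= 3).
#' @param classProportions length-3 nonnegative fractions summing to 1
#'   over (`R8_Lower`, `R8_Null`, `R8_Upper_Lower`); equal by default.
#' @param height,width image dimensions in pixels; at least 901 x 2201 so
#'   the canonical ROI coordinates apply unscaled (defaults 1200 x 2400).
#' @param noiseSigma Gaussian mottle standard deviation in gray levels.
#' @param mottlePoisson apply Poisson mottle before the Gaussian component.
#' @param molarContrast peak contrast of molar structures in gray levels.
#' @param tiltRange maximum absolute tilt of affected molars in degrees.
#' @param seed integer dataset seed; identical seed and config give a
#'   bit-identical dataset.
#' @return A [SyntheticConfig-class] object.
#' @export
syntheticConfig <- function(nImages = 150L,
                            classProportions = c(1, 1, 1) / 3,
                            height = 1200L, width = 2400L,
                            noiseSigma = 8, mottlePoisson = TRUE,
                            molarContrast = 60, tiltRange = 30,
                            seed = 42L) {
  new("SyntheticConfig", nImages = as.integer(nImages),
      classProportions = as.numeric(classProportions),
      height = as.integer(height), width = as.integer(width),
      noiseSigma = as.numeric(noiseSigma),
      mottlePoisson = isTRUE(mottlePoisson),
      molarContrast = as.numeric(molarContrast),
      tiltRange = as.numeric(tiltRange), seed = as.integer(seed))
}

# canonical third-molar site centers (1-based pixel coords) inside the
# unscaled ROI band rows [300, 900) x cols [490, 2200)
.molarSites <- function() {
  data.frame(
    site = c("upper_left", "upper_right", "lower_left", "lower_right"),
    row = c(456, 456, 761, 761),
    col = c(691, 1996, 756, 1936),
    jaw = c("upper", "upper", "lower", "lower"),
    stringsAsFactors = FALSE)
}

# linear interpolation matrix mapping g control points onto n pixels
.lerpMatrix <- function(n, g) {
  pos <- seq(1, n, length.out = g)
  M <- matrix(0, n, g)
  seg <- pmin(findInterval(seq_len(n), pos), g - 1L)
  t <- (seq_len(n) - pos[seg]) / (pos[seg + 1L] - pos[seg])
  M[cbind(seq_len(n), seg)] <- 1 - t
  M[cbind(seq_len(n), seg + 1L)] <- t
  M
}

# returns the additive intensity patch for rows rr, cols cc
.blobPatch <- function(rr, cc, r0, c0, ry, rx, tiltDeg, contrast, texture) {
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  th <- tiltDeg * pi / 180
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  e <- (u / ry)^2 + (v / rx)^2
  bump <- contrast * pmax(1 - e, 0)^0.5
  if (texture == "checker") {
    # checkerboard aligned with the tilt axis; 15 px squares keep their
    # crossings (corner features) through the 9x9 bilateral smoothing
    t <- 0.5 * contrast * sign(sin(2 * pi * u / 30) * sin(2 * pi * v / 30))
    bump <- bump + t * (e < 0.85)
  } else if (texture == "dots") {
    # lattice of small bright dots (radius 4.5, pitch 20), phased so one
    # sits at the center; under the edge detector each dot becomes an
    # isolated compact ring whose patch appearance is far from any
    # line-crossing pattern
    su <- ((u + 10) %% 20) - 10
    sv <- ((v + 10) %% 20) - 10
    bump <- bump + 1.0 * contrast *
      (su * su + sv * sv <= 20.25) * (e < 0.85)
  }
  bump
}


#' Render one synthetic panoramic radiograph
#'
#' @param config a [syntheticConfig()] (only the image-level fields are
#'   used, not `nImages`/`classProportions`).
#' @param label one of `R8_Lower`, `R8_Null`, `R8_Upper_Lower`.
#' @param seed per-image seed.
#' @return A list with `pixels` (integer matrix) and `sites` (data.frame
#'   with `site`, `row`, `col`, `tilt`, `present`).
#' @export
renderRadiograph <- function(config, label, seed) {
  label <- match.arg(label, MOLAR_CLASSES)
  h <- config@height; w <- config@width
  set.seed(as.integer(seed %% 2147483647))

  # low-frequency background and trabecular-bone-like blotch field,
  # composed at quarter resolution then block-upsampled; the blotches
  # (thresholded band-limited noise) have irregular rims that give every
  # image (including R8_Null) a baseline keypoint population
  h4 <- ceiling(h / 4); w4 <- ceiling(w / 4)
  grid <- matrix(stats::rnorm(12 * 24, mean = 100, sd = 18), 12, 24)
  base4 <- .lerpMatrix(h4, 12) %*% grid %*% t(.lerpMatrix(w4, 24))
  tg <- matrix(stats::rnorm(ceiling(h4 / 4) * ceiling(w4 / 4)),
               ceiling(h4 / 4), ceiling(w4 / 4))
  t4 <- .lerpMatrix(h4, nrow(tg)) %*% tg %*% t(.lerpMatrix(w4, ncol(tg)))
  base4 <- base4 + (t4 > 0.8) * (0.45 * config@molarContrast)
  img <- base4[rep(seq_len(h4), each = 4)[seq_len(h)],
               rep(seq_len(w4), each = 4)[seq_len(w)]]

  addBlob <- function(r0, c0, ry, rx, tilt, contrast, tex) {
    half <- ceiling(max(ry, rx)) + 8L
    rr <- max(1L, r0 - half):min(h, r0 + half)
    cc <- max(1L, c0 - half):min(w, c0 + half)
    img[rr, cc] <<- img[rr, cc] +
      .blobPatch(rr, cc, r0, c0, ry, rx, tilt, contrast, tex)
  }

  # distractor teeth along the arch, outside the molar sites
  for (dc in c(1050, 1180, 1310, 1440))
    addBlob(as.integer(0.52 * h), dc, 55, 28, 0,
            0.6 * config@molarContrast, "none")

  sites <- .molarSites()
  sites$present <- switch(label,
    R8_Null = c(FALSE, FALSE, FALSE, FALSE),
    R8_Lower = c(FALSE, FALSE, TRUE, TRUE),
    R8_Upper_Lower = c(TRUE, TRUE, TRUE, TRUE))
  sites$tilt <- 0
  for (i in seq_len(nrow(sites))) {
    tex <- "none"
    if (sites$present[i]) {
      sites$tilt[i] <- sample(c(-1, 1), 1) *
        stats::runif(1, 0.3 * config@tiltRange, max(config@tiltRange, 1e-9))
      tex <- if (sites$jaw[i] == "lower") "checker" else "dots"
    }
    addBlob(sites$row[i], sites$col[i], 70, 48, sites$tilt[i],
            config@molarContrast, tex)
  }

  # jaw-arch band, mottle, Gaussian noise and 8-bit quantisation
  arch <- 0.52 * h + 0.18 * h * ((seq_len(w) - w / 2) / (w / 2))^2
  pixels <- .render_finish_cpp(img, arch, 35, 0.05 * h,
                               config@mottlePoisson, config@noiseSigma)
  list(pixels = pixels,
       sites = sites[, c("site", "row", "col", "tilt", "present")])
}

# largest-remainder apportionment of n over proportions p
.classCounts <- function(n, p) {
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * p - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a labelled synthetic radiograph dataset on disk
#'
#' Writes one 8-bit grayscale PNG per image plus `manifest.csv`
#' (`path,label`) and `sites.csv` (ground-truth molar sites) under `dir`.
#' Class counts follow `classProportions` as closely as integer counts
#' allow (largest-remainder rounding); labels are interleaved so any
#' prefix of the manifest is approximately balanced. Identical config and
#' seed reproduce a bit-identical dataset.
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if missing).
#' @return A [SyntheticDataset-class].
#' @export
generateDataset <- function(config, dir) {
  methods::validObject(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- .classCounts(config@nImages, config@classProportions)
  # interleave classes: 1st of each class, then 2nd of each, ...
  labels <- unlist(lapply(seq_len(max(counts)), function(i)
    MOLAR_CLASSES[counts >= i]), use.names = FALSE)
  paths <- sprintf("img_%04d_%s.png", seq_along(labels), labels)
  siteList <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    r <- renderRadiograph(config, labels[i],
                          deriveSeed(config@seed, paste0("image", i)))
    writeRadiograph(r$pixels, file.path(dir, paths[i]))
    s <- r$sites
    s$image <- paths[i]
    siteList[[i]] <- s
  }
  manifest <- data.frame(path = paths, label = labels,
                         stringsAsFactors = FALSE)
  sites <- do.call(rbind, siteList)[, c("image", "site", "row", "col",
                                        "tilt", "present")]
  ds <- new("SyntheticDataset", manifest = manifest, sites = sites,
            config = config, dir = normalizePath(dir))
  writeManifest(ds, file.path(dir, "manifest.csv"))
  utils::write.csv(sites, file.path(dir, "sites.csv"), row.names = FALSE)
  ds
}

#' Write a `path,label` manifest CSV
#'
#' @param dataset a [SyntheticDataset-class] or a data.frame with columns
#'   `path` and `label` (paths relative to the manifest location).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeManifest <- function(dataset, path) {
  m <- if (is(dataset, "SyntheticDataset")) dataset@manifest else dataset
  if (!is.data.frame(m) || !all(c("path", "label") %in% names(m)) ||
      nrow(m) == 0)
    stop("manifest must be a non-empty data.frame with 'path' and 'label'")
  if (!all(m$label %in% MOLAR_CLASSES))
    stop("labels must be one of: ", paste(MOLAR_CLASSES, collapse = ", "))
  utils::write.csv(m[, c("path", "label")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and validate a `path,label` manifest CSV
#'
#' @param path manifest CSV path.
#' @return A data.frame with columns `path` and `label` and attribute
#'   `dir` (the manifest's directory, against which relative paths
#'   resolve).
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stop("manifest must have 'path' and 'label' columns")
  bad <- setdiff(unique(m$label), MOLAR_CLASSES)
  if (length(bad))
    stop("invalid label(s) ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(MOLAR_CLASSES, collapse = ", "))
  attr(m, "dir") <- dirname(normalizePath(path))
  m
}
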