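---
title: "Classifying third-molar complications with bag-of-visual-words histograms"
author: "molarBoVW"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying third-molar complications with bag-of-visual-words histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A panoramic dental radiograph shows both jaws in one wide-field image.
Third molars (wisdom teeth, "R8") sit at the four rear corners of the
dental arch; their impaction or tilt is a common complication that a
trained dentist reads off the radiograph in seconds. This package
implements a classical computer-vision pipeline that assigns a whole
radiograph to one of three groups — `R8_Lower` (lower third molars
affected), `R8_Null` (no complication), `R8_Upper_Lower` (upper and
lower affected) — without any localisation or bounding-box training:

1. **Smoothing and edge detection.** A 3×3 median filter suppresses
   quantum mottle; a bilateral filter (diameter 9, sigmaColor =
   sigmaSpace = 75) removes remaining noise while preserving edges;
   Sobel X and Y gradients are taken, converted to `uint8` by absolute
   value, and blended with equal weights into one edge image.
2. **Region of interest.** A fixed binary mask over rows `[300, 900)` ×
   columns `[490, 2200)` of a 1200×2400 radiograph — the band where all
   four third molars sit — restricts feature detection. The mask never
   crops: positions stay in the original frame.
3. **Local features.** ORB (default) or SIFT keypoints and descriptors
   are extracted inside the mask, at most 500 per image, kept by
   descending detector response.
4. **Bag of visual words.** All descriptors are pooled and clustered
   with K-means (Lloyd's algorithm, k-means++ seeding). The K cluster
   centers are the visual vocabulary; each image becomes a length-K
   histogram counting its descriptors' nearest centers. Positions are
   discarded — only texture statistics remain.
5. **Classification.** Six classifiers — multinomial logistic
   regression, RBF-kernel SVM, a one-hidden-layer (100 ReLU units) MLP,
   decision tree, gradient boosting, random forest — are compared under
   stratified 10-fold cross-validation, all sharing one fold
   assignment so the comparison is paired.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `medianKernel` | 3 | px | smallest kernel that removes single-pixel mottle |
| `bilateralDiameter` | 9 | px | window of the edge-preserving smoother |
| `sigmaColor`, `sigmaSpace` | 75, 75 | gray levels, px | published smoothing strength |
| `blendWx`, `blendWy` | 0.5, 0.5 | — | symmetric treatment of X and Y gradients |
| ROI | rows 300–900, cols 490–2200 | px | third-molar band on the 1200×2400 reference |
| `maxKeypoints` | 500 | per image | bounds vocabulary memory; keeps CV fold sizes meaningful |
| `vocabK` | 2800 (preset 200) | words | published vocabulary size; 200 for desk-scale synthetic runs |
| `nFolds` | 10 | — | published protocol |
| `globalSeed` | 42 | — | single seed reproducing a whole run |

Hyperparameters the published comparison leaves unstated (tree depth,
boosting rounds, SVM cost/γ, MLP optimiser) are pinned in
`classifierDefaults()` so every run is reproducible; they were chosen
once as ordinary textbook defaults, not searched.

Two detector settings deviate from the scikit-image stock values, for a
reason specific to this pipeline: features are detected on a *sparse
edge map*, not a natural image. `fast_threshold = 0.05` (stock 0.08)
lets FAST fire on the smooth-rimmed, low-contrast structures that
survive the smoothing chain, and `n_scales = 4` (stock 8) stops the top
pyramid levels — where a 2-megapixel edge map has been downscaled into
mush — from contributing unstable keypoints.

## Design choices where the contract was open

- **Border handling** of every windowed filter is reflect-101 padding.
  Zero padding would create a dark frame whose artificial edges spawn
  spurious keypoints at the image boundary.
- **"Converted back to uint8"** for signed gradients is implemented as
  absolute value followed by clipping, keeping both edge polarities;
  plain clipping would discard all negative-going edges.
- **Rounding** is half-up at every 8-bit conversion. One documented
  rule keeps the brute-force oracle tests exact; base R's
  round-half-even would make them flaky at `.5` boundaries.
- **Histogram normalisation** defaults to L1 (each histogram sums
  to 1) so images with different keypoint counts are comparable; raw
  counts are available via `normalize = FALSE`, and a zero-keypoint
  image keeps an all-zero histogram with the flag forced off.
- **Nearest-center ties** break to the lowest center index, and k-means
  empty clusters are re-seeded from the point farthest from its center
  — both for exact reproducibility.
- **Vocabulary scope**: by default one vocabulary is built from all
  images before cross-validation (the published protocol). This leaks
  descriptor information across folds; `strictCv = TRUE` rebuilds the
  vocabulary inside each training fold. The default follows the
  published recipe, the flag exists for users who want the
  leakage-free estimate.
- **Stratified folds**: the protocol only says "10 equivalent parts";
  with three classes of unknown balance, unstratified folds can lose a
  class entirely, so folds are stratified (per-class counts within one
  across folds) by dealing shuffled class members round-robin.
- **`mean ± std`** is the arithmetic mean and *population* standard
  deviation of the 10 fold accuracies, recomputable from the per-fold
  values embedded in every report.
- **Feature extraction input**: the pipeline feeds the blended edge
  image to the detector, matching the stage ordering of the
  architecture; `useEdgeImage = FALSE` switches to the smoothed
  pre-Sobel image for users who want to compare.
- **SURF** is accepted in configurations but has no implementation in
  the available backends; requesting it raises a capability error.
  Silent fallback to another detector would invalidate any comparison
  table built on top.

## The synthetic data generator

The clinical dataset behind this pipeline design is private, so the
package ships a seeded phantom generator (`generateDataset()`) that
reproduces the *statistical structure* the pipeline relies on, not the
anatomy:

- a smooth low-frequency background (bilinearly upsampled coarse
  Gaussian noise) plus a U-shaped jaw-arch band;
- a trabecular-bone-like blotch field (thresholded band-limited noise
  at 0.45× the molar contrast) whose irregular rims give every image —
  including `R8_Null` — a baseline keypoint population;
- four molar sites at canonical coordinates inside the ROI band;
  affected sites are tilted (uniform up to `tiltRange`, default 30°)
  and textured;
- Poisson mottle (variance proportional to intensity, the quantum-noise
  model) followed by additive Gaussian noise (`noiseSigma`, default 8
  gray levels), then half-up quantisation to 8 bits.

Because BoVW discards positions, class identity must be carried by
*local texture*, and the textures must survive the package's own
smoothing chain and detector. The choices are deliberate:

- lower affected sites carry a **checkerboard** (period 30 px): its
  crossings are ideal corner features;
- upper affected sites carry a **bright dot lattice** (radius 4.5 px,
  pitch 20 px, full molar contrast): under the edge detector each dot
  becomes a compact isolated ring, a patch appearance far from any
  line-crossing pattern, so its descriptors quantise into different
  visual words than the checkerboard's.

Earlier candidates failed instructively: fine stripes are erased by
the 9×9 bilateral window; straight-edged textures give FAST nothing to
fire on; near-symmetric blobs get arbitrary ORB orientations and their
descriptors scatter across words. The blotch contrast (0.45×) is set
so blotch corners win the response ranking only in `R8_Null` images —
in textured images the 500 keypoint slots are filled by site texture,
keeping the class-specific words pure.

What passing tests on these phantoms shows: the pipeline's stages
compose correctly, the encoding preserves class-discriminative texture
statistics, and the CV harness measures real signal (the permuted-label
control collapses to chance). What it does not show: performance on
clinical radiographs, whose class signal (impaction geometry, root
morphology) is subtler and positionally structured; the fixed ROI and
texture assumptions do not transfer. The generator also requires
images at least 901×2201 so the canonical ROI coordinates apply
unscaled; site layout is calibrated to the 1200×2400 reference
geometry (at 901 px height the jaw-arch band overlaps the upper
sites, weakening their texture).

## Numerical and degenerate-input behaviour

- Filters are exact against brute-force double-loop oracles (median,
  Sobel) or within one gray level (bilateral, rounding).
- Lloyd iterations never increase inertia (asserted per run); with
  `K` equal to the number of distinct points, inertia is 0.
- Constant images yield zero keypoints; all-false masks yield zero
  keypoints; both produce a defined all-zero histogram and, at
  prediction time, a `lowEvidence` flag rather than an error.
- Unreadable images in a batch are logged per image and skipped; a run
  fails only if every image fails.
- Vocabulary and descriptor container files are fail-closed: a
  truncated block is a corruption error, never a partial object.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
synthetic preset: 150 images of 1200×2400 at K = 200, which exercises
roughly 75,000 descriptors and completes in a few minutes on one CPU.
The published vocabulary size (K = 2800) is supported and used by
default for real datasets; it simply needs a descriptor pool larger
than desk-scale synthetic runs provide.

## Known limitations

- The ORB/SIFT backends come from scikit-image via a subprocess
  bridge; a Python interpreter with scikit-image must be on `PATH`
  (or named in `MOLARBOVW_PYTHON`). SURF is unavailable.
- ORB's binary descriptors are clustered in real space (bytes cast to
  reals) with Euclidean distance, matching the uniform K-means recipe
  across extractors; Hamming-space clustering would respect the
  descriptor metric better and is deliberately not offered.
- The default (non-strict) CV shares one vocabulary across folds and
  therefore carries a mild optimistic bias.
- Accuracy is the headline metric; confusion matrices are emitted for
  diagnosis but no probability calibration is attempted.
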