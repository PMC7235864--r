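# Shared fixtures, built once per test run. The small dataset keeps the
# reference 1200 x 2400 geometry (site textures and the jaw-arch band
# are laid out for it) but only a handful of images.

.fixtures <- new.env(parent = emptyenv())

smallSynthConfig <- function(nImages = 6L, seed = 11L) {
  syntheticConfig(nImages = nImages, seed = seed)
}

smallDataset <- function() {
  if (is.null(.fixtures$dataset)) {
    dir <- file.path(tempdir(), "molarBoVW-fixture-data")
    .fixtures$dataset <- generateDataset(smallSynthConfig(), dir)
  }
  .fixtures$dataset
}

smallBatch <- function() {
  if (is.null(.fixtures$batch)) {
    ds <- smallDataset()
    mf <- datasetManifest(ds)
    attr(mf, "dir") <- datasetDir(ds)
    .fixtures$batch <- batchExtract(mf)
  }
  .fixtures$batch
}
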