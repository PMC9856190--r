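library(SummarizedExperiment)

# Shared fixtures, built once per test run. The default cohort (42 samples,
# 420 points) takes ~30 s to synthesize and preprocess; several acceptance
# checks reuse it.
.fixtures <- new.env(parent = emptyenv())

defaultCohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- synthCohort(synthConfig(), seed = 1)
  .fixtures$cohort
}

defaultPreprocessed <- function() {
  if (is.null(.fixtures$prep))
    .fixtures$prep <- preprocessSpectra(defaultCohort())
  .fixtures$prep
}

defaultImages <- function() {
  if (is.null(.fixtures$images))
    .fixtures$images <- encodeCohort(defaultPreprocessed())
  .fixtures$images
}

# A tiny cohort for structural tests.
smallCohort <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- synthCohort(
      synthConfig(n_cancerous = 2, n_normal = 2, n_paracancerous = 1,
                  points_per_sample = 2), seed = 11)
  .fixtures$small
}

# Deterministic random test image in [0, 1].
randomImage <- function(seed = 1) {
  withr::with_seed(seed, array(runif(100 * 100 * 3), c(100, 100, 3)))
}

# A small image set with two clearly separable classes (red vs blue).
separableImages <- function(n_per_class = 24) {
  n <- 2L * n_per_class
  pix <- array(as.raw(0), c(100, 100, 3, n))
  red <- array(0, c(100, 100, 3)); red[, , 1] <- 0.9
  blue <- array(0, c(100, 100, 3)); blue[, , 3] <- 0.9
  withr::with_seed(42, {
    for (i in seq_len(n_per_class))
      pix[, , , i] <- as.raw(round(pmin(pmax(
        red + array(rnorm(3e4, 0, 0.03), dim(red)), 0), 1) * 255))
    for (i in n_per_class + seq_len(n_per_class))
      pix[, , , i] <- as.raw(round(pmin(pmax(
        blue + array(rnorm(3e4, 0, 0.03), dim(blue)), 0), 1) * 255))
  })
  EncodedImageSet(pix, rep(c(0L, 1L), each = n_per_class))
}
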