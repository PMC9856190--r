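#' Image augmentation primitives
#'
#' Elementary label-preserving transforms of a `100 x 100 x 3` image array
#' in `[0, 1]`: horizontal/vertical flips, rotations by multiples of 90
#' degrees, and additive Gaussian noise (non-zero mean) clipped to `[0, 1]`.
#'
#' @param img numeric array `h x w x 3` (square for rotations).
#' @param axis `"horizontal"` (mirror columns) or `"vertical"` (mirror
#'   rows).
#' @return transformed image array of identical shape.
#' @export
flipImage <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") img[, dim(img)[2]:1, , drop = FALSE]
  else img[dim(img)[1]:1, , , drop = FALSE]
}

#' @rdname flipImage
#' @param k number of 90-degree rotations (1, 2 or 3).
#' @export
rotateImage <- function(img, k = 1) {
  stopifnot(k %in% 1:3, dim(img)[1] == dim(img)[2])
  for (i in seq_len(k)) {
    img <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , , drop = FALSE]
  }
  img
}

#' @rdname flipImage
#' @param mean,sigma noise mean and s.d. (pixel units; the defaults follow
#'   the augmentation recipe of non-zero-mean Gaussian noise).
#' @export
addImageNoise <- function(img, mean = 0.1, sigma = 0.05) {
  noise <- array(rnorm(length(img), mean, sigma), dim(img))
  pmin(pmax(img + noise, 0), 1)
}

# The eight augmentation operations used for class balancing.
.AUG_OPS <- c("flip_h", "flip_v", "rot90", "rot180", "rot270",
              "noise_0.1", "noise_0.2", "noise_0.3")

.applyAug <- function(img, op, noise_sigma = 0.05) {
  switch(op,
         flip_h = flipImage(img, "horizontal"),
         flip_v = flipImage(img, "vertical"),
         rot90 = rotateImage(img, 1),
         rot180 = rotateImage(img, 2),
         rot270 = rotateImage(img, 3),
         noise_0.1 = addImageNoise(img, 0.1, noise_sigma),
         noise_0.2 = addImageNoise(img, 0.2, noise_sigma),
         noise_0.3 = addImageNoise(img, 0.3, noise_sigma),
         stop("unknown augmentation op: ", op))
}

#' Expand and balance an image set by augmentation
#'
#' Expands each class to exactly `n_per_class` images: all originals are
#' retained and the remainder is produced by cycling through the originals
#' and applying one of the eight augmentations (horizontal/vertical flip;
#' 90/180/270-degree rotation; Gaussian noise with mean 0.1, 0.2 or 0.3),
#' drawn uniformly at random. Provenance (`source` index into the input,
#' `op`) is recorded in the metadata.
#'
#' @param x an [EncodedImageSet-class] (e.g. the training images of a fold).
#' @param n_per_class target count per class (default 5000).
#' @param seed RNG seed.
#' @param noise_sigma s.d. of the noise augmentations.
#' @return a balanced [EncodedImageSet-class] with
#'   `2 * n_per_class` images.
#' @export
expandToN <- function(x, n_per_class = 5000, seed = 1, noise_sigma = 0.05) {
  labs <- unique(imageLabels(x))
  if (!all(c(0L, 1L) %in% labs)) stop("both classes must be present")
  withr::with_seed(seed, {
    keep <- list()
    for (lab in c(0L, 1L)) {
      orig <- which(imageLabels(x) == lab)
      if (n_per_class < length(orig))
        stop("n_per_class smaller than the number of originals for label ", lab)
      n_extra <- n_per_class - length(orig)
      src <- rep(orig, length.out = n_extra)
      ops <- sample(.AUG_OPS, n_extra, replace = TRUE)
      keep[[as.character(lab)]] <- list(orig = orig, src = src, ops = ops)
    }
    n_out <- 2 * n_per_class
    pix <- array(as.raw(0), c(100, 100, 3, n_out))
    labels <- integer(n_out)
    meta <- vector("list", n_out)
    j <- 0
    in_meta <- imageMeta(x)
    mval <- function(col, i) {
      v <- in_meta[[col]]
      if (is.null(v)) NA else v[i]
    }
    mkMeta <- function(i, op) DataFrame(
      patient_id = mval("patient_id", i), sample_id = mval("sample_id", i),
      tissue_class = mval("tissue_class", i), point_id = mval("point_id", i),
      source = i, op = op)
    for (lab in c("0", "1")) {
      k <- keep[[lab]]
      for (i in k$orig) {
        j <- j + 1
        pix[, , , j] <- x@pixels[, , , i]
        labels[j] <- as.integer(lab)
        meta[[j]] <- mkMeta(i, "original")
      }
      for (e in seq_along(k$src)) {
        j <- j + 1
        i <- k$src[e]
        img <- .applyAug(imagePixels(x, i), k$ops[e], noise_sigma)
        pix[, , , j] <- as.raw(round(img * 255))
        labels[j] <- as.integer(lab)
        meta[[j]] <- mkMeta(i, k$ops[e])
      }
    }
    EncodedImageSet(pix, labels, do.call(rbind, meta))
  })
}

#' Stratified train/validation split
#'
#' Splits image indices into training and validation sets, stratified by
#' label, in the given ratio.
#'
#' @param labels integer 0/1 labels.
#' @param ratio training fraction (default 0.7).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `val` (disjoint,
#'   union = all indices).
#' @export
splitTrainVal <- function(labels, ratio = 0.7, seed = 1) {
  stopifnot(ratio > 0, ratio < 1)
  withr::with_seed(seed, {
    train <- integer(0)
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      train <- c(train, sample(idx, floor(ratio * length(idx))))
    }
    train <- sort(train)
    list(train = train, val = setdiff(seq_along(labels), train))
  })
}
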