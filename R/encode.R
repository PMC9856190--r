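#' Assemble a detection point's polarization matrix
#'
#' Stacks the 12 preprocessed polarized spectra of one detection point into
#' a 12 x n_channels matrix, rows in ascending angle order (0, 30, ...,
#' 330 degrees).
#'
#' @param x a [RamanSpectra-class] holding the point's polarized spectra
#'   (a conventional spectrum, if present, is ignored).
#' @return numeric matrix `12 x n_channels` with the point metadata in
#'   attributes `patient_id`, `sample_id`, `tissue_class`, `point_id`.
#' @export
assembleMatrix <- function(x) {
  pol <- x[, !is.na(x$polarization_deg)]
  angles <- pol$polarization_deg
  missing <- setdiff(.POLAR_ANGLES, angles)
  if (length(missing))
    stop("missing polarization angle(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(angles)) stop("duplicated polarization angles")
  pol <- pol[, order(angles)]
  m <- t(assay(pol, "intensity"))
  rownames(m) <- sprintf("a%03d", .POLAR_ANGLES)
  structure(m, patient_id = pol$patient_id[1], sample_id = pol$sample_id[1],
            tissue_class = pol$tissue_class[1], point_id = pol$point_id[1])
}

#' Density slicing
#'
#' Clips a matrix to a per-matrix percentile range and quantizes it
#' uniformly to `n_levels` integer levels `0 .. n_levels - 1`. A constant
#' matrix maps to all-zero levels. The percentile clipping makes the levels
#' invariant under any constant offset of the input.
#'
#' @param m numeric matrix (the polarization matrix).
#' @param n_levels number of quantization levels (>= 2, default 64).
#' @param clip lower/upper clip percentiles (default `c(1, 99)`).
#' @return integer matrix of levels, same shape, with attributes preserved.
#' @export
densitySlice <- function(m, n_levels = 64, clip = c(1, 99)) {
  stopifnot(n_levels >= 2, length(clip) == 2, clip[1] < clip[2])
  q <- quantile(m, clip / 100, names = FALSE)
  lev <- if (q[2] <= q[1]) {
    array(0L, dim(m))
  } else {
    v <- pmin(pmax(m, q[1]), q[2])
    matrix(pmin(as.integer(floor((v - q[1]) / (q[2] - q[1]) * n_levels)),
                n_levels - 1L), nrow(m), ncol(m))
  }
  attrs <- attributes(m)[c("patient_id", "sample_id", "tissue_class", "point_id")]
  attributes(lev) <- c(attributes(lev), attrs[!vapply(attrs, is.null, TRUE)])
  attr(lev, "n_levels") <- n_levels
  lev
}

# 256-entry jet-like RGB lookup table (piecewise-linear blue-cyan-yellow-red).
.jetLUT <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      u <- (0:255) / 255
      ramp <- function(x) pmin(pmax(x, 0), 1)
      lut <<- round(cbind(r = ramp(1.5 - abs(4 * u - 3)),
                          g = ramp(1.5 - abs(4 * u - 2)),
                          b = ramp(1.5 - abs(4 * u - 1))) * 255) / 255
    }
    lut
  }
})

.COLORMAPS <- c("jet", "gray")

# Area-interpolation (box-average) resize weights: n_out x n_in row-stochastic.
.areaResizeWeights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    a <- (i - 1) * scale
    b <- i * scale
    j0 <- floor(a) + 1
    j1 <- min(ceiling(b), n_in)
    for (j in j0:j1)
      W[i, j] <- max(0, min(b, j) - max(a, j - 1))
  }
  W / scale
}

#' Pseudo-color encoding of a level matrix
#'
#' Maps quantized levels through a fixed 256-entry RGB lookup table, then
#' resizes the 12 x n_channels color matrix to 100 x 100 by area (box
#' average) interpolation. Pixels are quantized once to 8-bit resolution,
#' so writing and re-reading a PNG reproduces them exactly.
#'
#' @param levels integer level matrix from [densitySlice()].
#' @param colormap `"jet"` (default) or `"gray"`.
#' @param size output image side length (default 100).
#' @return numeric array `size x size x 3` with values in `[0, 1]`
#'   (multiples of 1/255), metadata attributes preserved.
#' @export
toPseudocolor <- function(levels, colormap = "jet", size = 100) {
  colormap <- match.arg(colormap, .COLORMAPS)
  n_levels <- attr(levels, "n_levels")
  if (is.null(n_levels)) n_levels <- max(levels) + 1L
  lut <- if (colormap == "jet") .jetLUT() else
    cbind((0:255) / 255, (0:255) / 255, (0:255) / 255)
  idx <- round(levels / (n_levels - 1) * 255) + 1L
  Wr <- .areaResizeWeights(nrow(levels), size)
  Wc <- .areaResizeWeights(ncol(levels), size)
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    plane <- matrix(lut[idx, ch], nrow(levels), ncol(levels))
    img[, , ch] <- Wr %*% plane %*% t(Wc)
  }
  img <- round(img * 255) / 255
  attrs <- attributes(levels)[c("patient_id", "sample_id", "tissue_class",
                                "point_id")]
  attributes(img) <- c(attributes(img), attrs[!vapply(attrs, is.null, TRUE)])
  img
}

#' Encode a cohort as pseudo-color images
#'
#' For every detection point of the selected tissue classes, assembles the
#' 12-angle polarization matrix, density-slices it and encodes it as a
#' 100 x 100 pseudo-color image. Labels follow the discrimination
#' convention: cancerous = 0, normal = 1.
#'
#' @param x a preprocessed cohort ([RamanSpectra-class]).
#' @param classes tissue classes to encode (default cancerous + normal,
#'   the two discrimination classes).
#' @param n_levels,clip,colormap see [densitySlice()] and [toPseudocolor()].
#' @return an [EncodedImageSet-class].
#' @export
encodeCohort <- function(x, classes = c("cancerous", "normal"),
                         n_levels = 64, clip = c(1, 99), colormap = "jet") {
  xs <- x[, x$tissue_class %in% classes & !is.na(x$polarization_deg)]
  key <- paste(xs$sample_id, xs$point_id, sep = "|")
  pts <- unique(key)
  n <- length(pts)
  pix <- array(as.raw(0), c(100, 100, 3, n))
  labels <- integer(n)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- key == pts[i]
    m <- assembleMatrix(xs[, sel])
    img <- toPseudocolor(densitySlice(m, n_levels, clip), colormap)
    pix[, , , i] <- as.raw(round(img * 255))
    labels[i] <- if (attr(m, "tissue_class") == "cancerous") 0L else 1L
    meta[[i]] <- DataFrame(patient_id = attr(m, "patient_id"),
                           sample_id = attr(m, "sample_id"),
                           tissue_class = attr(m, "tissue_class"),
                           point_id = attr(m, "point_id"),
                           source = NA_integer_, op = "original")
  }
  EncodedImageSet(pix, labels, do.call(rbind, meta))
}

#' Write / read encoded images as PNG
#'
#' Images are written as 8-bit RGB PNG named
#' `<patient>_<sample>_<point>_<label>.png`, together with an index CSV
#' (`index.csv`: path, label, patient_id, sample_id, point_id).
#'
#' @param x an [EncodedImageSet-class].
#' @param dir output directory (created if needed).
#' @return `writeImagePNG`: invisibly, the index data.frame;
#'   `readImagePNG`: an [EncodedImageSet-class].
#' @export
writeImagePNG <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nImages(x)
  meta <- imageMeta(x)
  path <- character(n)
  for (i in seq_len(n)) {
    path[i] <- file.path(dir, sprintf("%s_%s_%02d_%d.png",
                                      meta$patient_id[i], meta$sample_id[i],
                                      meta$point_id[i], x@labels[i]))
    png::writePNG(imagePixels(x, i), path[i])
  }
  idx <- data.frame(path = path, label = x@labels,
                    patient_id = meta$patient_id, sample_id = meta$sample_id,
                    point_id = meta$point_id)
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(dir) {
  idx <- read.csv(file.path(dir, "index.csv"))
  n <- nrow(idx)
  pix <- array(as.raw(0), c(100, 100, 3, n))
  for (i in seq_len(n)) {
    img <- png::readPNG(idx$path[i])
    pix[, , , i] <- as.raw(round(img * 255))
  }
  EncodedImageSet(pix, idx$label,
                  DataFrame(patient_id = idx$patient_id,
                            sample_id = idx$sample_id,
                            tissue_class = ifelse(idx$label == 0L,
                                                  "cancerous", "normal"),
                            point_id = idx$point_id,
                            source = NA_integer_, op = "original"))
}
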