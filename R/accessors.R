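#' Accessors for RamanSpectra and EncodedImageSet
#'
#' Small accessors returning per-spectrum metadata and grid information, so
#' user code never reaches into slots.
#'
#' @param x a [RamanSpectra-class] or [EncodedImageSet-class] object.
#' @param i image index.
#' @return `wavenumbers`: the channel wavenumber vector (cm^-1);
#'   `polarizationAngle`: angle in degrees, `NA` for conventional spectra;
#'   `imagePixels`: a `100 x 100 x 3` double array in `[0, 1]`.
#' @name RamanSpectra-accessors
NULL

#' @rdname RamanSpectra-accessors
#' @export
setMethod("wavenumbers", "RamanSpectra",
          function(x) rowData(x)$wavenumber)

#' @rdname RamanSpectra-accessors
#' @export
setMethod("tissueClass", "RamanSpectra", function(x) x$tissue_class)

#' @rdname RamanSpectra-accessors
#' @export
setMethod("tissueComponent", "RamanSpectra", function(x) x$component)

#' @rdname RamanSpectra-accessors
#' @export
setMethod("polarizationAngle", "RamanSpectra", function(x) x$polarization_deg)

#' @rdname RamanSpectra-accessors
#' @export
setMethod("patientId", "RamanSpectra", function(x) x$patient_id)

#' @rdname RamanSpectra-accessors
#' @export
setMethod("sampleId", "RamanSpectra", function(x) x$sample_id)

#' @rdname RamanSpectra-accessors
#' @export
setMethod("pointId", "RamanSpectra", function(x) x$point_id)

setMethod("show", "RamanSpectra", function(object) {
  cat("RamanSpectra:", nrow(object), "channels x", ncol(object), "spectra\n")
  wn <- wavenumbers(object)
  if (length(wn))
    cat(sprintf("  grid: %.0f-%.0f cm-1 (%d channels)\n",
                min(wn), max(wn), length(wn)))
  if (ncol(object)) {
    cat("  classes:", paste(sprintf("%s=%d", names(table(object$tissue_class)),
                                    table(object$tissue_class)), collapse = " "), "\n")
    npol <- sum(!is.na(object$polarization_deg))
    cat("  polarized:", npol, " conventional:", ncol(object) - npol, "\n")
  }
  invisible(NULL)
})

#' @rdname RamanSpectra-accessors
#' @export
setMethod("imageLabels", "EncodedImageSet", function(x) x@labels)

#' @rdname RamanSpectra-accessors
#' @export
setMethod("imageMeta", "EncodedImageSet", function(x) x@meta)

#' @rdname RamanSpectra-accessors
#' @export
setMethod("nImages", "EncodedImageSet", function(x) dim(x@pixels)[4])

#' @rdname RamanSpectra-accessors
#' @export
setMethod("imagePixels", "EncodedImageSet", function(x, i) {
  stopifnot(length(i) == 1, i >= 1, i <= nImages(x))
  array(as.integer(x@pixels[, , , i]) / 255, dim = c(100, 100, 3))
})

#' Subset an EncodedImageSet by image index
#' @param x an [EncodedImageSet-class].
#' @param i integer or logical index over images.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EncodedImageSet", function(x, i, j, ..., drop = FALSE) {
  if (is.logical(i)) i <- which(i)
  new("EncodedImageSet",
      pixels = x@pixels[, , , i, drop = FALSE],
      labels = x@labels[i],
      meta = x@meta[i, , drop = FALSE])
})

setMethod("show", "EncodedImageSet", function(object) {
  n <- nImages(object)
  cat("EncodedImageSet: ", n, " images (100 x 100 x 3, 8-bit)\n", sep = "")
  if (n) cat("  labels: cancerous(0)=", sum(object@labels == 0L),
             " normal(1)=", sum(object@labels == 1L), "\n", sep = "")
  invisible(NULL)
})
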