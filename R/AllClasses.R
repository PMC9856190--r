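#' RamanSpectra: a container for Raman spectra on a shared wavenumber grid
#'
#' `RamanSpectra` extends [SummarizedExperiment::SummarizedExperiment] for
#' Raman spectra. Rows are spectral channels (with a `wavenumber` column in
#' `rowData`), columns are individual spectra. `colData` records, per spectrum:
#' `patient_id`, `sample_id`, `tissue_class` (`"normal"`, `"paracancerous"` or
#' `"cancerous"`), `component` (`"protein"` or `"lipid"`), `point_id` (the
#' detection point within a sample) and `polarization_deg` (polarization angle
#' in degrees; `NA` marks a conventional, non-polarized spectrum).
#'
#' @slot .. see `SummarizedExperiment`; the first assay must be named
#'   `"intensity"`.
#' @aliases RamanSpectra-class
#' @export
setClass("RamanSpectra", contains = "SummarizedExperiment")

.TISSUE_CLASSES <- c("normal", "paracancerous", "cancerous")
.COMPONENTS <- c("protein", "lipid")
.COLDATA_REQUIRED <- c("patient_id", "sample_id", "tissue_class",
                       "component", "point_id", "polarization_deg")

setValidity("RamanSpectra", function(object) {
  msg <- character()
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (!"wavenumber" %in% colnames(rowData(object))) {
    msg <- c(msg, "rowData must contain a 'wavenumber' column")
  } else {
    wn <- rowData(object)$wavenumber
    if (length(wn) > 1) {
      d <- diff(wn)
      if (any(d <= 0)) msg <- c(msg, "wavenumber grid must be strictly increasing")
      if (diff(range(d)) > 1e-6 * mean(d))
        msg <- c(msg, "wavenumber grid must be uniformly spaced")
    }
  }
  missing_cols <- setdiff(.COLDATA_REQUIRED, colnames(colData(object)))
  if (length(missing_cols))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missing_cols, collapse = ", ")))
  if ("tissue_class" %in% colnames(colData(object)) &&
      !all(object$tissue_class %in% .TISSUE_CLASSES))
    msg <- c(msg, "tissue_class must be normal, paracancerous or cancerous")
  if ("component" %in% colnames(colData(object)) &&
      !all(object$component %in% .COMPONENTS))
    msg <- c(msg, "component must be protein or lipid")
  if (ncol(object) && any(!is.finite(assay(object, "intensity"))))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a RamanSpectra object
#'
#' @param intensity numeric matrix, channels x spectra.
#' @param wavenumber numeric vector of channel wavenumbers (cm^-1), one per
#'   row of `intensity`.
#' @param colData a `DataFrame`/`data.frame` of per-spectrum metadata with
#'   columns `patient_id`, `sample_id`, `tissue_class`, `component`,
#'   `point_id`, `polarization_deg` (`NA` = conventional).
#' @param metadata optional list stored in the object metadata.
#' @return A [RamanSpectra-class] object.
#' @examples
#' grid <- wavenumberGrid(n_channels = 50)
#' m <- matrix(runif(100), nrow = 50)
#' cd <- S4Vectors::DataFrame(patient_id = c("p1", "p1"), sample_id = "s1",
#'   tissue_class = "normal", component = "protein", point_id = 1L,
#'   polarization_deg = c(0, NA))
#' rs <- RamanSpectra(m, grid, cd)
#' @export
RamanSpectra <- function(intensity, wavenumber, colData, metadata = list()) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(wavenumber))
    stop("nrow(intensity) must equal length(wavenumber)")
  cd <- as(colData, "DataFrame")
  if (is.null(colnames(intensity)))
    colnames(intensity) <- sprintf("spec%04d", seq_len(ncol(intensity)))
  rownames(cd) <- colnames(intensity)
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(wavenumber = wavenumber),
    colData = cd, metadata = metadata)
  new("RamanSpectra", se)
}

#' EncodedImageSet: 100 x 100 RGB pseudo-color images with labels
#'
#' Stores encoded polarization-matrix images as 8-bit RGB (a `raw` array of
#' dim `c(100, 100, 3, n)`), a 0/1 label per image (0 = cancerous,
#' 1 = normal) and per-image metadata. Pixel values are recovered in `[0, 1]`
#' with [imagePixels()].
#'
#' @slot pixels raw array, `100 x 100 x 3 x n`, 8-bit pixel codes.
#' @slot labels integer vector of 0/1 labels.
#' @slot meta `DataFrame` of per-image metadata (patient, sample, point,
#'   provenance of augmented images).
#' @aliases EncodedImageSet-class
#' @export
setClass("EncodedImageSet",
         representation(pixels = "array", labels = "integer",
                        meta = "DataFrame"))

setValidity("EncodedImageSet", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 4 || !all(d[1:3] == c(100, 100, 3)))
    msg <- c(msg, "pixels must be a 100 x 100 x 3 x n array")
  if (typeof(object@pixels) != "raw")
    msg <- c(msg, "pixels must be stored as raw (8-bit)")
  if (length(object@labels) != d[4])
    msg <- c(msg, "one label per image required")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 (cancerous) or 1 (normal)")
  if (nrow(object@meta) != d[4])
    msg <- c(msg, "meta must have one row per image")
  if (length(msg)) msg else TRUE
})

#' @rdname EncodedImageSet-class
#' @param pixels raw or numeric array `100 x 100 x 3 x n` (numeric values in
#'   `[0, 1]` are quantized to 8 bits).
#' @param labels integer 0/1 labels, one per image.
#' @param meta optional per-image metadata.
#' @export
EncodedImageSet <- function(pixels, labels, meta = NULL) {
  if (is.double(pixels)) {
    d <- dim(pixels)
    pixels <- array(as.raw(pmin(pmax(round(pixels * 255), 0), 255)), d)
  }
  labels <- as.integer(labels)
  if (is.null(meta))
    meta <- DataFrame(row.names = seq_along(labels))
  meta <- as(meta, "DataFrame")
  new("EncodedImageSet", pixels = pixels, labels = labels, meta = meta)
}
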