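#' Per-class band-area table
#'
#' Mean and standard deviation of trough-baseline band areas over all
#' qualifying spectra, per band and tissue class, for one component and
#' acquisition mode. "Polarized" selects the parallel (0 degree) spectra,
#' "conventional" the non-polarized ones.
#'
#' @param x a preprocessed [RamanSpectra-class] (baseline-corrected,
#'   normalized).
#' @param bands numeric band centers (cm^-1). Defaults to the component's
#'   standard band set.
#' @param component `"protein"` or `"lipid"`.
#' @param mode `"polarized"` (0 degrees) or `"conventional"`.
#' @return data.frame with columns `band_center`, `tissue_class`, `mode`,
#'   `n`, `mean_area`, `sd_area`. Class/band combinations without spectra
#'   are flagged by `n = 0` and `NA` statistics.
#' @export
bandAreaTable <- function(x, bands = NULL,
                          component = c("protein", "lipid"),
                          mode = c("polarized", "conventional")) {
  component <- match.arg(component)
  mode <- match.arg(mode)
  if (is.null(bands))
    bands <- as.numeric(names(
      if (component == "protein") .PROTEIN_FWHM else .LIPID_FWHM))
  sel <- x$component == component &
    (if (mode == "polarized") !is.na(x$polarization_deg) &
       x$polarization_deg == 0 else is.na(x$polarization_deg))
  xs <- x[, sel]
  out <- expand.grid(band_center = bands, tissue_class = .TISSUE_CLASSES,
                     stringsAsFactors = FALSE)
  out$mode <- mode
  stats <- lapply(seq_len(nrow(out)), function(i) {
    cls <- xs[, xs$tissue_class == out$tissue_class[i]]
    if (!ncol(cls)) return(c(n = 0, mean_area = NA_real_, sd_area = NA_real_))
    a <- suppressWarnings(bandArea(cls, out$band_center[i]))
    c(n = length(a), mean_area = mean(a),
      sd_area = if (length(a) > 1) sd(a) else 0)
  })
  out <- cbind(out, do.call(rbind, stats))
  out[order(out$band_center, out$tissue_class), ]
}

#' Welch two-sample t-test for band areas
#'
#' Two-sided unequal-variance (Welch) t-test comparing band areas between
#' two groups of spectra. When both groups have zero variance and equal
#' means the test is degenerate and `p = 1` is returned by convention (and
#' `p = 0` for unequal means).
#'
#' @param areas_a,areas_b numeric vectors (each length >= 2, finite).
#' @return list with elements `t` and `p`.
#' @examples
#' ttestBand(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))  # t = -5, p ~ 0.00105
#' @export
ttestBand <- function(areas_a, areas_b) {
  stopifnot(length(areas_a) >= 2, length(areas_b) >= 2,
            all(is.finite(areas_a)), all(is.finite(areas_b)))
  if (sd(areas_a) == 0 && sd(areas_b) == 0) {
    eq <- isTRUE(all.equal(mean(areas_a), mean(areas_b)))
    return(list(t = if (eq) 0 else sign(mean(areas_a) - mean(areas_b)) * Inf,
                p = if (eq) 1 else 0))
  }
  ht <- t.test(areas_a, areas_b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Band-wise significance table (cancerous vs normal)
#'
#' Reproduces the difference analysis between cancerous and normal tissue:
#' a Welch t-test on per-spectrum band areas, for both parallel-polarized
#' and conventional spectra.
#'
#' @inheritParams bandAreaTable
#' @return data.frame with columns `band_center`, `mode`, `t`, `p`.
#' @export
significanceTable <- function(x, bands = NULL,
                              component = c("protein", "lipid")) {
  component <- match.arg(component)
  if (is.null(bands))
    bands <- as.numeric(names(
      if (component == "protein") .PROTEIN_FWHM else .LIPID_FWHM))
  res <- lapply(c("polarized", "conventional"), function(mode) {
    sel <- x$component == component &
      (if (mode == "polarized") !is.na(x$polarization_deg) &
         x$polarization_deg == 0 else is.na(x$polarization_deg))
    xs <- x[, sel]
    ca <- xs[, xs$tissue_class == "cancerous"]
    no <- xs[, xs$tissue_class == "normal"]
    do.call(rbind, lapply(bands, function(b) {
      tt <- ttestBand(suppressWarnings(bandArea(ca, b)),
                      suppressWarnings(bandArea(no, b)))
      data.frame(band_center = b, mode = mode, t = tt$t, p = tt$p)
    }))
  })
  do.call(rbind, res)
}

#' Amide III bimodal ratio across polarization angles
#'
#' The amide III band of collagen has a bimodal structure with sub-peaks at
#' 1247 and 1269 cm^-1. Their trough-corrected height ratio I1247/I1269
#' tracks collagen fiber orientation: in normal tissue it is below 1 in
#' parallel (0 degree) polarization and above 1 in perpendicular (90
#' degree), while in cancerous tissue it stays below 1 at every angle.
#'
#' @param x a preprocessed [RamanSpectra-class] holding one detection
#'   point's polarization series (protein component), e.g. from
#'   [pointSeries()].
#' @return data.frame with columns `angle_deg` and `ratio` (12 rows,
#'   ascending angle); a zero 1269 height yields `NA` for that angle.
#' @export
bimodalRatioCurve <- function(x) {
  pol <- x[, !is.na(x$polarization_deg)]
  if (!ncol(pol)) stop("no polarized spectra in input")
  if (!all(pol$component == "protein"))
    stop("bimodal ratio is defined for protein spectra")
  ord <- order(pol$polarization_deg)
  pol <- pol[, ord]
  h1247 <- peakHeight(pol, 1247)
  h1269 <- peakHeight(pol, 1269)
  ratio <- ifelse(h1269 > 0, h1247 / h1269, NA_real_)
  data.frame(angle_deg = pol$polarization_deg, ratio = ratio)
}

#' Mean bimodal-ratio curves per tissue class
#'
#' Averages the per-point bimodal ratio curves of all protein points of
#' each tissue class.
#'
#' @param x a preprocessed cohort ([RamanSpectra-class]).
#' @return data.frame with columns `tissue_class`, `angle_deg`, `mean_ratio`,
#'   `sd_ratio`, `n_points`.
#' @export
meanRatioCurves <- function(x) {
  prot <- x[, x$component == "protein" & !is.na(x$polarization_deg)]
  key <- paste(prot$sample_id, prot$point_id)
  out <- list()
  for (cl in .TISSUE_CLASSES) {
    cls <- prot[, prot$tissue_class == cl]
    if (!ncol(cls)) next
    pts <- unique(paste(cls$sample_id, cls$point_id))
    curves <- vapply(pts, function(k) {
      sel <- paste(cls$sample_id, cls$point_id) == k
      rc <- bimodalRatioCurve(cls[, sel])
      rc$ratio[order(rc$angle_deg)]
    }, numeric(12))
    out[[cl]] <- data.frame(
      tissue_class = cl, angle_deg = .POLAR_ANGLES,
      mean_ratio = rowMeans(curves, na.rm = TRUE),
      sd_ratio = apply(curves, 1, sd, na.rm = TRUE),
      n_points = length(pts))
  }
  do.call(rbind, out)
}

#' Class-average spectrum
#'
#' Channel-wise mean of the selected spectra, as used for analyses defined
#' on average spectra (averaging suppresses channel noise, so trough-
#' baseline quantities on the mean spectrum are nearly noise-free).
#'
#' @param x a [RamanSpectra-class].
#' @return numeric vector (length = number of channels).
#' @export
meanSpectrum <- function(x) {
  if (!ncol(x)) stop("no spectra to average")
  rowMeans(assay(x, "intensity"))
}

#' Hydroxyproline/proline band-area ratio
#'
#' Ratio of trough-baseline band areas I875/I921 (hydroxyproline over
#' proline): a relative increase marks higher collagen hydroxylation.
#'
#' @param x preprocessed numeric spectrum or [RamanSpectra-class]
#'   (ratio per column).
#' @param grid wavenumber grid (numeric input only).
#' @return numeric ratio(s); `NA` when the 921 area is 0.
#' @export
hydroxyprolineRatio <- function(x, grid = NULL) {
  a875 <- suppressWarnings(bandArea(x, 875, grid = grid))
  a921 <- suppressWarnings(bandArea(x, 921, grid = grid))
  ifelse(a921 > 0, a875 / a921, NA_real_)
}

#' Lipid unsaturation ratio
#'
#' Trough-corrected peak-height ratio I1652/I1442 on a lipid spectrum: the
#' C=C stretch relative to the CH2 deformation, a proxy for the unsaturated
#' to saturated fatty-acid balance, which rises with cancerization.
#'
#' @inheritParams hydroxyprolineRatio
#' @return numeric ratio(s).
#' @export
unsaturationRatio <- function(x, grid = NULL) {
  h1652 <- peakHeight(x, 1652, grid = grid)
  h1442 <- peakHeight(x, 1442, grid = grid)
  ifelse(h1442 > 0, h1652 / h1442, NA_real_)
}

#' Plot mean bimodal-ratio curves
#'
#' @param curves output of [meanRatioCurves()].
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the reshaped matrix of mean ratios.
#' @export
plotRatioCurves <- function(curves, ...) {
  classes <- unique(curves$tissue_class)
  m <- vapply(classes, function(cl)
    curves$mean_ratio[curves$tissue_class == cl], numeric(12))
  graphics::matplot(.POLAR_ANGLES, m, type = "b", pch = 16, lty = 1,
                    xlab = "polarization angle (deg)",
                    ylab = "I1247 / I1269", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topleft", legend = classes, col = seq_along(classes),
                   pch = 16, bty = "n")
  invisible(m)
}
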