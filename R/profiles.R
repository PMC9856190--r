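#' @name tissue-profiles
#' @title Synthetic tissue band profiles
#'
#' @description
#' Default band parameterization of the synthetic generator. Each tissue
#' class (normal, paracancerous, cancerous) has a protein and a lipid
#' spectral component; each component is a set of pseudo-Voigt bands with an
#' isotropic amplitude `a_iso`, an anisotropic amplitude `a_aniso` and an
#' orientation angle, so the band height at polarization angle theta follows
#' a Malus-type law `a_iso + a_aniso * cos^2(theta - orientation)`.
#'
#' The default amplitudes are calibrated so that, after fluorescence-baseline
#' removal, reference-band normalization (1450 cm^-1 for protein, 1442 cm^-1
#' for lipid) and trough-baseline integration, the mean band areas of a
#' default cohort reproduce published per-class band-area magnitudes of
#' breast tissue, and the amide III bimodal ratio I1247/I1269 shows the
#' characteristic anisotropy pattern: below 1 at 0 degrees and above 1 at 90
#' degrees in normal and paracancerous tissue, below 1 at every angle in
#' cancerous tissue. The amide I band sits at 1660 cm^-1 in normal and
#' paracancerous profiles and shifts to 1656 cm^-1 in the cancerous profile.
NULL

# Band centers (cm^-1) and widths (fwhm, cm^-1), shared across classes.
# The amide III sub-bands get strongly different widths (broad 1247, narrow
# 1269): this reconciles area magnitudes (which scale with width) with peak
# heights (which set the bimodal ratio).
.PROTEIN_FWHM <- c(`875` = 14, `921` = 14, `1003` = 9, `1032` = 12,
                   `1247` = 26, `1269` = 7, `1302` = 10, `1318` = 10,
                   `1450` = 40, `1660` = 38)
.LIPID_FWHM <- c(`871` = 12, `971` = 14, `1032` = 10, `1084` = 16,
                 `1269` = 16, `1302` = 16, `1442` = 36, `1652` = 20,
                 `1745` = 14)

# Per-class width overrides: the cancerous amide III alpha-helix sub-band
# (1269 cm^-1) is sharpened, which together with its raised amplitude keeps
# the cancerous I1247/I1269 height ratio below 1 at every polarization
# angle while the band areas stay at their calibrated magnitudes.
.FWHM_OVERRIDES <- list(
  protein = list(cancerous = c(`1269` = 5.5)),
  lipid = list())

# Calibration targets: mean trough-baseline band area (after normalization)
# per band, class and mode ("par" = parallel-polarized 0 degrees, "conv" =
# conventional). Units: intensity x cm^-1 on the normalized scale.
.PROTEIN_AREA_TARGETS <- data.frame(
  center = c(875, 921, 1003, 1032, 1247, 1269, 1302, 1318, 1450, 1660),
  cancerous_par  = c(1.03, 1.17, 4.16, 2.40, 4.85, 2.05, 0.37, 0.18, 40.82, 49.99),
  cancerous_conv = c(1.09, 1.34, 4.78, 2.46, 4.85, 1.78, 0.32, 0.24, 39.07, 56.52),
  normal_par     = c(1.22, 1.46, 4.33, 2.99, 4.61, 2.05, 0.13, 0.27, 43.94, 48.21),
  normal_conv    = c(1.15, 1.49, 4.90, 3.10, 6.00, 1.55, 0.25, 0.29, 42.20, 48.68),
  paracancerous_par  = c(1.22, 1.46, 4.33, 2.99, 4.10, 2.30, 0.13, 0.27, 43.94, 48.21),
  paracancerous_conv = c(1.15, 1.49, 4.90, 3.10, 5.00, 1.70, 0.25, 0.29, 42.20, 48.68))

.LIPID_AREA_TARGETS <- data.frame(
  center = c(871, 971, 1032, 1084, 1269, 1302, 1442, 1652, 1745),
  cancerous_par  = c(0.24, 1.06, 1.18, 1.36, 6.94, 8.47, 37.55, 17.54, 2.98),
  cancerous_conv = c(0.63, 1.23, 0.76, 2.12, 7.89, 8.72, 38.91, 19.93, 3.98),
  normal_par     = c(0.43, 1.49, 1.31, 1.72, 6.81, 8.68, 36.89, 14.21, 1.89),
  normal_conv    = c(0.64, 1.31, 0.83, 2.25, 8.08, 8.52, 37.33, 18.43, 3.15),
  paracancerous_par  = c(0.43, 1.49, 1.31, 1.72, 6.81, 8.68, 36.89, 14.21, 1.89),
  paracancerous_conv = c(0.64, 1.31, 0.83, 2.25, 8.08, 8.52, 37.33, 18.43, 3.15))

#' Band profile constructor
#'
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param a_iso isotropic amplitude (>= 0).
#' @param a_aniso anisotropic amplitude (`a_iso + a_aniso` >= 0).
#' @param orientation_deg orientation angle phi in `[0, 180)`.
#' @param shape_mix Gaussian fraction of the pseudo-Voigt lineshape in
#'   `[0, 1]` (1 = pure Gaussian).
#' @return one-row data.frame of band parameters.
#' @export
bandProfile <- function(center, fwhm, a_iso, a_aniso = 0,
                        orientation_deg = 0, shape_mix = 1) {
  stopifnot(fwhm > 0, a_iso >= 0, a_iso + a_aniso >= 0,
            orientation_deg >= 0, orientation_deg < 180,
            shape_mix >= 0, shape_mix <= 1)
  data.frame(center = center, fwhm = fwhm, a_iso = a_iso, a_aniso = a_aniso,
             orientation_deg = orientation_deg, shape_mix = shape_mix)
}

#' Tissue profile constructor
#'
#' A tissue profile bundles the band set of one tissue class and spectral
#' component with its fluorescence-background and noise settings.
#'
#' @param tissue_class one of `"normal"`, `"paracancerous"`, `"cancerous"`.
#' @param component `"protein"` or `"lipid"`.
#' @param bands data.frame of band parameters (rows as from [bandProfile()]).
#'   Protein profiles must include bands at 1003 and 1247 cm^-1, lipid
#'   profiles at 1084 and 1745 cm^-1 (the marker bands used by
#'   [classifyComponent()]).
#' @param baseline_rel_amp range of the fluorescence-background amplitude,
#'   relative to the largest band height (default 5-10x).
#' @param baseline_order polynomial order of the background (default 5).
#' @param noise_sigma Gaussian noise s.d.; default 1% of the largest band
#'   amplitude.
#' @return an object of class `"TissueProfile"`.
#' @export
tissueProfile <- function(tissue_class, component, bands,
                          baseline_rel_amp = c(5, 10), baseline_order = 5,
                          noise_sigma = NULL) {
  tissue_class <- match.arg(tissue_class, .TISSUE_CLASSES)
  component <- match.arg(component, .COMPONENTS)
  stopifnot(is.data.frame(bands),
            all(c("center", "fwhm", "a_iso", "a_aniso",
                  "orientation_deg", "shape_mix") %in% names(bands)),
            all(bands$fwhm > 0), all(bands$a_iso >= 0),
            all(bands$a_iso + bands$a_aniso >= 0))
  markers <- if (component == "protein") c(1003, 1247) else c(1084, 1745)
  if (!all(vapply(markers, function(m) any(abs(bands$center - m) < 6),
                  logical(1))))
    stop(component, " profile must contain marker bands at ",
         paste(markers, collapse = " and "), " cm^-1")
  max_amp <- max(bands$a_iso + pmax(bands$a_aniso, 0))
  if (is.null(noise_sigma)) noise_sigma <- 0.01 * max_amp
  structure(list(tissue_class = tissue_class, component = component,
                 bands = bands, baseline_rel_amp = baseline_rel_amp,
                 baseline_order = baseline_order, noise_sigma = noise_sigma,
                 max_amp = max_amp),
            class = "TissueProfile")
}

# Convert (parallel amplitude, conventional amplitude) to the cos^2-law
# parameters. The conventional amplitude is the angular mean a_iso +
# a_aniso/2; the orientation is 0 when the band is brighter parallel,
# 90 degrees otherwise.
.ampsToBand <- function(par_amp, conv_amp) {
  if (par_amp >= conv_amp) {
    a_aniso <- 2 * (par_amp - conv_amp)
    a_iso <- 2 * conv_amp - par_amp
    phi <- 0
  } else {
    a_iso <- par_amp
    a_aniso <- 2 * (conv_amp - par_amp)
    phi <- 90
  }
  if (a_iso < 0) stop("inconsistent amplitudes: conventional < parallel/2")
  list(a_iso = a_iso, a_aniso = a_aniso, orientation_deg = phi)
}

#' Default tissue profiles
#'
#' The six default profiles (3 classes x 2 components) with calibrated band
#' amplitudes. See the package vignette for how the defaults were chosen.
#'
#' @param tissue_class,component select one profile.
#' @return a `"TissueProfile"`.
#' @examples
#' p <- defaultTissueProfile("cancerous", "protein")
#' p$bands[, c("center", "a_iso", "a_aniso", "orientation_deg")]
#' @export
defaultTissueProfile <- function(tissue_class = .TISSUE_CLASSES,
                                 component = .COMPONENTS) {
  tissue_class <- match.arg(tissue_class)
  component <- match.arg(component)
  targets <- if (component == "protein") .PROTEIN_AREA_TARGETS else .LIPID_AREA_TARGETS
  fwhm <- if (component == "protein") .PROTEIN_FWHM else .LIPID_FWHM
  ovr <- .FWHM_OVERRIDES[[component]][[tissue_class]]
  if (!is.null(ovr)) fwhm[names(ovr)] <- ovr
  gains <- .ampGains()[[component]][[tissue_class]]
  par_a <- targets[[paste0(tissue_class, "_par")]] * gains$par
  conv_a <- targets[[paste0(tissue_class, "_conv")]] * gains$conv
  bands <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    ab <- .ampsToBand(par_a[i], conv_a[i])
    center <- targets$center[i]
    # amide I red-shifts from 1660 to 1656 cm^-1 in the cancerous profile
    if (component == "protein" && center == 1660 && tissue_class == "cancerous")
      center <- 1656
    bandProfile(center, unname(fwhm[as.character(targets$center[i])]),
                ab$a_iso, ab$a_aniso, ab$orientation_deg)
  }))
  tissueProfile(tissue_class, component, bands)
}

#' @export
print.TissueProfile <- function(x, ...) {
  cat("TissueProfile:", x$tissue_class, x$component, "-", nrow(x$bands),
      "bands, noise sigma", signif(x$noise_sigma, 3), "\n")
  invisible(x)
}
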