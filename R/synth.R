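#' Band amplitude at a polarization angle
#'
#' Malus-type cos-squared anisotropy law: the height of a band at linear
#' polarization angle `theta` is
#' `a_iso + a_aniso * cos^2(theta - orientation)`. The law is 180-degree
#' periodic and its circular mean over angles is `a_iso + a_aniso / 2`, which
#' is the amplitude used for conventional (non-polarized) spectra.
#'
#' @param band one row of band parameters (as from [bandProfile()]) or any
#'   list with `a_iso`, `a_aniso`, `orientation_deg`.
#' @param theta polarization angle(s) in degrees, in `[0, 360)`.
#' @return numeric amplitude(s).
#' @examples
#' b <- bandProfile(1247, 12, a_iso = 1, a_aniso = 2, orientation_deg = 0)
#' bandAmplitudeAtAngle(b, 60)  # 1 + 2 * cos(60 deg)^2 = 1.5
#' @export
bandAmplitudeAtAngle <- function(band, theta) {
  stopifnot(all(theta >= 0), all(theta < 360))
  band$a_iso + band$a_aniso * cos((theta - band$orientation_deg) * pi / 180)^2
}

.POLAR_ANGLES <- seq(0, 330, by = 30)

# Pseudo-Voigt lineshape matrix: channels x bands, unit peak height.
.lineshapeMatrix <- function(grid, bands) {
  L <- matrix(0, length(grid), nrow(bands))
  for (i in seq_len(nrow(bands))) {
    d <- grid - bands$center[i]
    f <- bands$fwhm[i]
    gauss <- exp(-4 * log(2) * (d / f)^2)
    lorentz <- 1 / (1 + 4 * (d / f)^2)
    L[, i] <- bands$shape_mix[i] * gauss + (1 - bands$shape_mix[i]) * lorentz
  }
  L
}

# Random non-negative polynomial fluorescence background. A degree-`order`
# polynomial in the scaled coordinate, shifted to be non-negative and scaled
# to a peak amplitude of `amp`.
.randomBaseline <- function(grid, order, amp) {
  u <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  co <- runif(order + 1, -1, 1)
  p <- drop(outer(u, 0:order, `^`) %*% co)
  p <- p - min(p)
  m <- max(p)
  if (m < 1e-12) rep(amp, length(grid)) else p * (amp / m)
}

#' Synthesize one spectrum
#'
#' Band heights follow the cos-squared law at a polarization angle, or its
#' circular mean for a conventional spectrum; bands are summed as
#' pseudo-Voigt lineshapes, a smooth polynomial fluorescence background is
#' added, then i.i.d. Gaussian noise; intensities are truncated at 0.
#'
#' @param profile a `"TissueProfile"` (see [tissueProfile()],
#'   [defaultTissueProfile()]).
#' @param theta polarization angle in degrees, or `"conventional"`.
#' @param grid wavenumber grid (see [wavenumberGrid()]).
#' @param baseline optional fixed background vector (length of `grid`); if
#'   `NULL` a random one is drawn. `0` disables the background.
#' @param amp_factors optional per-band multiplicative factors (length =
#'   number of bands), used by [synthCohort()] for sample/point
#'   heterogeneity.
#' @param noise logical; add Gaussian noise (sd = `profile$noise_sigma`)?
#' @param metadata named list merged into the spectrum metadata.
#' @return a one-column [RamanSpectra-class].
#' @export
synthSpectrum <- function(profile, theta = "conventional",
                          grid = wavenumberGrid(), baseline = NULL,
                          amp_factors = NULL, noise = TRUE,
                          metadata = list()) {
  stopifnot(inherits(profile, "TissueProfile"))
  y <- .synthIntensities(profile, theta, grid, baseline, amp_factors, noise)
  ang <- if (identical(theta, "conventional")) NA_real_ else as.numeric(theta)
  md <- modifyList(list(patient_id = "p1", sample_id = "s1", point_id = 1L),
                   metadata)
  cd <- DataFrame(patient_id = md$patient_id, sample_id = md$sample_id,
                  tissue_class = profile$tissue_class,
                  component = profile$component,
                  point_id = md$point_id, polarization_deg = ang)
  RamanSpectra(matrix(y, ncol = 1), grid, cd)
}

.synthIntensities <- function(profile, theta, grid, baseline = NULL,
                              amp_factors = NULL, noise = TRUE,
                              L = NULL) {
  bands <- profile$bands
  if (is.null(L)) L <- .lineshapeMatrix(grid, bands)
  if (nrow(bands) && nrow(L) != length(grid))
    stop("lineshape matrix does not match the grid")
  amps <- if (identical(theta, "conventional")) {
    bands$a_iso + bands$a_aniso / 2
  } else {
    bandAmplitudeAtAngle(bands, as.numeric(theta))
  }
  if (!is.null(amp_factors)) amps <- amps * amp_factors
  y <- if (nrow(bands)) drop(L %*% amps) else numeric(length(grid))
  if (is.null(baseline)) {
    amp <- runif(1, profile$baseline_rel_amp[1], profile$baseline_rel_amp[2]) *
      profile$max_amp
    baseline <- .randomBaseline(grid, profile$baseline_order, amp)
  }
  y <- y + baseline
  if (noise && profile$noise_sigma > 0)
    y <- y + rnorm(length(grid), 0, profile$noise_sigma)
  pmax(y, 0)
}

#' Synthesize one detection point (a polarization series)
#'
#' Emits the 12 polarized spectra at 0, 30, ..., 330 degrees plus one
#' conventional spectrum, sharing patient/sample/point metadata and (within
#' the point) the same fluorescence background, so that with noise off the
#' conventional spectrum is exactly the angular mean of the 12 polarized
#' spectra.
#'
#' @inheritParams synthSpectrum
#' @return a 13-column [RamanSpectra-class] (12 angles + conventional).
#' @export
synthPoint <- function(profile, grid = wavenumberGrid(), amp_factors = NULL,
                       noise = TRUE, metadata = list()) {
  stopifnot(inherits(profile, "TissueProfile"))
  L <- .lineshapeMatrix(grid, profile$bands)
  amp <- runif(1, profile$baseline_rel_amp[1], profile$baseline_rel_amp[2]) *
    profile$max_amp
  baseline <- .randomBaseline(grid, profile$baseline_order, amp)
  thetas <- c(as.list(.POLAR_ANGLES), list("conventional"))
  Y <- vapply(thetas, function(th)
    .synthIntensities(profile, th, grid, baseline, amp_factors, noise, L),
    numeric(length(grid)))
  md <- modifyList(list(patient_id = "p1", sample_id = "s1", point_id = 1L),
                   metadata)
  cd <- DataFrame(patient_id = md$patient_id, sample_id = md$sample_id,
                  tissue_class = profile$tissue_class,
                  component = profile$component, point_id = md$point_id,
                  polarization_deg = c(.POLAR_ANGLES, NA_real_))
  RamanSpectra(Y, grid, cd)
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the emulated study design: 20 cancerous, 10 normal and 12
#' paracancerous samples, 10 detection points per sample, half of the points
#' probing the protein component and half the lipid component. Patients are
#' indexed so that cancerous sample i, normal sample i and paracancerous
#' sample i come from patient i (every patient contributes a cancerous
#' sample; the first `n_normal` also contribute normal tissue, the first
#' `n_paracancerous` paracancerous tissue).
#'
#' @param n_cancerous,n_normal,n_paracancerous per-class sample counts.
#' @param points_per_sample detection points per sample.
#' @param protein_fraction fraction of points probing the protein component.
#' @param sample_jitter_sd,point_jitter_sd s.d. (log scale) of the
#'   mean-corrected lognormal per-band amplitude heterogeneity between
#'   samples and between points.
#' @param noise logical; add channel noise.
#' @param grid wavenumber grid.
#' @return config list for [synthCohort()].
#' @export
synthConfig <- function(n_cancerous = 20, n_normal = 10, n_paracancerous = 12,
                        points_per_sample = 10, protein_fraction = 0.5,
                        sample_jitter_sd = 0.20, point_jitter_sd = 0.10,
                        noise = TRUE, grid = wavenumberGrid()) {
  if (n_cancerous < 0 || n_normal < 0 || n_paracancerous < 0 ||
      n_cancerous + n_normal + n_paracancerous <= 0)
    stop("sample counts must be non-negative, with at least one sample")
  if (points_per_sample <= 0) stop("points_per_sample must be positive")
  if (protein_fraction < 0 || protein_fraction > 1)
    stop("protein_fraction must be in [0, 1]")
  list(n_cancerous = n_cancerous, n_normal = n_normal,
       n_paracancerous = n_paracancerous,
       points_per_sample = points_per_sample,
       protein_fraction = protein_fraction,
       sample_jitter_sd = sample_jitter_sd,
       point_jitter_sd = point_jitter_sd,
       noise = noise, grid = grid)
}

#' Synthesize a cohort of polarized Raman spectra
#'
#' Generates every detection point of every sample as a polarization series
#' (12 angles + conventional), with per-sample and per-point band-amplitude
#' heterogeneity. Bit-reproducible for a fixed seed.
#'
#' @param config from [synthConfig()].
#' @param seed integer RNG seed.
#' @return a [RamanSpectra-class] with
#'   `(n_samples * points_per_sample * 13)` columns; `metadata()` records
#'   the config and seed.
#' @examples
#' \donttest{
#' rs <- synthCohort(synthConfig(n_cancerous = 1, n_normal = 1,
#'   n_paracancerous = 0, points_per_sample = 2), seed = 1)
#' ncol(rs)  # 2 samples x 2 points x 13 spectra
#' }
#' @export
synthCohort <- function(config = synthConfig(), seed = 1) {
  grid <- config$grid
  classes <- rep(c("cancerous", "normal", "paracancerous"),
                 c(config$n_cancerous, config$n_normal, config$n_paracancerous))
  class_idx <- unlist(lapply(
    c(config$n_cancerous, config$n_normal, config$n_paracancerous), seq_len))
  profiles <- lapply(.TISSUE_CLASSES, function(cl)
    lapply(.COMPONENTS, defaultTissueProfile, tissue_class = cl))
  names(profiles) <- .TISSUE_CLASSES
  for (cl in .TISSUE_CLASSES) names(profiles[[cl]]) <- .COMPONENTS
  lineshapes <- lapply(profiles, function(p)
    lapply(p, function(pr) .lineshapeMatrix(grid, pr$bands)))
  n_protein <- round(config$protein_fraction * config$points_per_sample)
  point_components <- rep(c("protein", "lipid"),
                          c(n_protein, config$points_per_sample - n_protein))

  withr::with_seed(seed, {
    blocks <- vector("list", length(classes))
    cds <- vector("list", length(classes))
    for (s in seq_along(classes)) {
      cl <- classes[s]
      patient <- sprintf("p%02d", class_idx[s])
      sample_id <- sprintf("%s_s%02d", substr(cl, 1, 4), class_idx[s])
      # per-sample band heterogeneity, one factor per band and component
      sfac <- lapply(profiles[[cl]], function(pr)
        .lnJitter(nrow(pr$bands), config$sample_jitter_sd))
      pt_blocks <- vector("list", config$points_per_sample)
      pt_cds <- vector("list", config$points_per_sample)
      for (pt in seq_len(config$points_per_sample)) {
        comp <- point_components[pt]
        pr <- profiles[[cl]][[comp]]
        pfac <- sfac[[comp]] * .lnJitter(nrow(pr$bands), config$point_jitter_sd)
        amp <- runif(1, pr$baseline_rel_amp[1], pr$baseline_rel_amp[2]) *
          pr$max_amp
        baseline <- .randomBaseline(grid, pr$baseline_order, amp)
        thetas <- c(as.list(.POLAR_ANGLES), list("conventional"))
        Y <- vapply(thetas, function(th)
          .synthIntensities(pr, th, grid, baseline, pfac, config$noise,
                            lineshapes[[cl]][[comp]]),
          numeric(length(grid)))
        pt_blocks[[pt]] <- Y
        pt_cds[[pt]] <- DataFrame(
          patient_id = patient, sample_id = sample_id, tissue_class = cl,
          component = comp, point_id = pt,
          polarization_deg = c(.POLAR_ANGLES, NA_real_))
      }
      blocks[[s]] <- do.call(cbind, pt_blocks)
      cds[[s]] <- do.call(rbind, pt_cds)
    }
    intensity <- do.call(cbind, blocks)
    cd <- do.call(rbind, cds)
    colnames(intensity) <- sprintf("%s_pt%02d_%s", cd$sample_id, cd$point_id,
                                   ifelse(is.na(cd$polarization_deg), "conv",
                                          sprintf("a%03d", cd$polarization_deg)))
    RamanSpectra(intensity, grid, cd,
                 metadata = list(seed = seed,
                                 config = config[setdiff(names(config), "grid")]))
  })
}

# Mean-corrected lognormal factors: E[factor] = 1.
.lnJitter <- function(n, sdlog) {
  if (sdlog <= 0) return(rep(1, n))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Extract one detection point's polarization series
#'
#' @param x a [RamanSpectra-class].
#' @param sample_id,point_id identify the point.
#' @return the 13-column subset (12 angles, ascending, + conventional).
#' @export
pointSeries <- function(x, sample_id, point_id) {
  sel <- x$sample_id == sample_id & x$point_id == point_id
  if (!any(sel)) stop("no spectra for ", sample_id, " point ", point_id)
  y <- x[, sel]
  ord <- order(is.na(y$polarization_deg), y$polarization_deg)
  y[, ord]
}
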