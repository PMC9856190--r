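#' Iterative modified-polynomial fluorescence baseline removal
#'
#' The broad tissue autofluorescence background is estimated by iterative
#' modified polynomial fitting: fit a polynomial to the spectrum, replace
#' every point lying above the fit by the fit, and repeat until the fit
#' stops changing (maximum relative change below `tol`) or `max_iter` is
#' reached. Raman peaks, which sit above the smooth background, are
#' progressively excluded, so the final fit tracks the fluorescence floor.
#'
#' @param x a numeric spectrum or a [RamanSpectra-class] (all columns
#'   corrected at once).
#' @param poly_order polynomial order (default 5).
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance: maximum absolute change of the fit
#'   between iterations, relative to the maximum absolute input intensity.
#' @return for a numeric `x`: a list with `corrected`, `baseline`,
#'   `n_iterations`, `converged` (`corrected + baseline` reconstructs the
#'   input). For a `RamanSpectra`: a new object whose `intensity` assay is
#'   the corrected signal, with a `baseline` assay and per-spectrum
#'   `baseline_n_iterations` / `baseline_converged` columns in `colData`.
#' @examples
#' g <- wavenumberGrid(n_channels = 200)
#' y <- 5 + 0.001 * (g - 1000)^2 / 100 + exp(-((g - 1200) / 10)^2)
#' fit <- removeBaseline(y, grid = g)
#' fit$converged
#' @param grid wavenumber grid (numeric input only; used for the polynomial
#'   basis).
#' @export
removeBaseline <- function(x, ...) UseMethod("removeBaseline")

#' @param ... passed on to methods.
#' @rdname removeBaseline
#' @export
removeBaseline.default <- function(x, ...) {
  stop("removeBaseline expects a numeric spectrum or a RamanSpectra object")
}

#' @export
removeBaseline.numeric <- function(x, poly_order = 5, max_iter = 100,
                                   tol = 1e-3,
                                   grid = wavenumberGrid(n_channels = length(x)),
                                   ...) {
  if (any(!is.finite(x))) stop("non-finite intensities")
  res <- .imodpolyFit(matrix(x, ncol = 1), grid, poly_order, max_iter, tol)
  list(corrected = drop(res$corrected), baseline = drop(res$baseline),
       n_iterations = res$n_iterations[1], converged = res$converged[1])
}

#' @export
removeBaseline.RamanSpectra <- function(x, poly_order = 5, max_iter = 100,
                                        tol = 1e-3, ...) {
  Y <- assay(x, "intensity")
  if (any(!is.finite(Y))) stop("non-finite intensities")
  res <- .imodpolyFit(Y, wavenumbers(x), poly_order, max_iter, tol)
  assays(x) <- list(intensity = res$corrected, baseline = res$baseline)
  x$baseline_n_iterations <- res$n_iterations
  x$baseline_converged <- res$converged
  x
}

# Vectorized iterative modified polyfit over the columns of Y, using an
# orthonormal polynomial basis (numerically stable up to high orders).
.imodpolyFit <- function(Y, grid, poly_order, max_iter, tol) {
  stopifnot(poly_order >= 1, max_iter >= 1, tol > 0)
  u <- (grid - mean(grid)) / (max(grid) - min(grid))
  B <- cbind(1 / sqrt(length(u)), stats::poly(u, degree = poly_order))
  B <- qr.Q(qr(B))                     # orthonormal columns
  scale_ref <- pmax(apply(abs(Y), 2, max), .Machine$double.eps)
  W <- Y
  fit <- B %*% crossprod(B, W)
  n_it <- rep(NA_integer_, ncol(Y))
  active <- rep(TRUE, ncol(Y))
  it <- 1
  while (any(active) && it <= max_iter) {
    W[, active] <- pmin(W[, active, drop = FALSE], fit[, active, drop = FALSE])
    newfit <- B %*% crossprod(B, W[, active, drop = FALSE])
    delta <- apply(abs(newfit - fit[, active, drop = FALSE]), 2, max) /
      scale_ref[active]
    fit[, active] <- newfit
    done <- delta < tol
    n_it[which(active)[done]] <- it
    active[which(active)[done]] <- FALSE
    it <- it + 1
  }
  converged <- !is.na(n_it)
  n_it[!converged] <- max_iter
  dimnames(fit) <- dimnames(Y)
  list(corrected = Y - fit, baseline = fit,
       n_iterations = n_it, converged = converged)
}

#' Classify a spectrum as protein or lipid
#'
#' Uses the marker bands: phenylalanine (1003 cm^-1) and amide III
#' (1247 cm^-1) appear only in protein spectra, while 1084 cm^-1 (C-O-C
#' stretch) and 1745 cm^-1 (ester C=O stretch) mark lipid spectra. The
#' spectrum is protein if the summed trough-corrected heights of the protein
#' markers exceed those of the lipid markers.
#'
#' @param x baseline-corrected numeric spectrum, or [RamanSpectra-class]
#'   (classified column-wise).
#' @param grid wavenumber grid (numeric input only).
#' @return `"protein"` or `"lipid"` (vector for `RamanSpectra`).
#' @export
classifyComponent <- function(x, grid = NULL) {
  if (is(x, "RamanSpectra")) {
    Y <- assay(x, "intensity")
    g <- wavenumbers(x)
    return(vapply(seq_len(ncol(Y)),
                  function(j) .classifyOne(Y[, j], g), character(1)))
  }
  if (is.null(grid)) grid <- wavenumberGrid(n_channels = length(x))
  .classifyOne(x, grid)
}

.classifyOne <- function(y, grid) {
  h <- function(ctr) peakHeight(y, ctr, grid = grid)
  if (h(1003) + h(1247) > h(1084) + h(1745)) "protein" else "lipid"
}

#' Normalize to the reference band
#'
#' Divides a baseline-corrected spectrum by the maximum intensity within
#' +/- 8 cm^-1 of the component reference band: 1450 cm^-1 (CH2/CH3
#' deformation) for protein, 1442 cm^-1 (CH2 deformation) for lipid. The
#' reference maximum becomes 1.
#'
#' @param x baseline-corrected numeric spectrum or [RamanSpectra-class].
#' @param component `"protein"` or `"lipid"`; for a `RamanSpectra` the
#'   default (`NULL`) takes each spectrum's `component` column.
#' @param grid wavenumber grid (numeric input only).
#' @param halfwidth half-width of the reference search window (cm^-1).
#' @return the normalized spectrum/object.
#' @export
normalizeReference <- function(x, component = NULL, grid = NULL,
                               halfwidth = 8) {
  ref_of <- function(comp) if (comp == "protein") 1450 else 1442
  if (is(x, "RamanSpectra")) {
    comps <- if (is.null(component)) x$component else
      rep(component, length.out = ncol(x))
    Y <- assay(x, "intensity")
    g <- wavenumbers(x)
    for (j in seq_len(ncol(Y))) {
      win <- abs(g - ref_of(comps[j])) <= halfwidth
      m <- max(Y[win, j])
      if (m <= 0) stop("degenerate spectrum ", colnames(x)[j],
                       ": non-positive reference band")
      Y[, j] <- Y[, j] / m
    }
    assay(x, "intensity") <- Y
    return(x)
  }
  if (is.null(component))
    stop("component is required for a numeric spectrum")
  component <- match.arg(component, .COMPONENTS)
  if (is.null(grid)) grid <- wavenumberGrid(n_channels = length(x))
  win <- abs(grid - ref_of(component)) <= halfwidth
  m <- max(x[win])
  if (m <= 0) stop("degenerate spectrum: non-positive reference band")
  x / m
}

#' Preprocess a cohort
#'
#' Convenience wrapper: baseline removal then reference-band normalization
#' using each spectrum's component label.
#'
#' @param x a [RamanSpectra-class].
#' @param ... passed to [removeBaseline()].
#' @return the preprocessed [RamanSpectra-class].
#' @export
preprocessSpectra <- function(x, ...) {
  normalizeReference(removeBaseline(x, ...))
}

# Default search half-width per band center: 20 cm^-1, narrowed for bands
# that sit in close doublets so the window maximum is the band's own peak
# (amide III 1247/1269, 22 cm^-1 apart; CH2 twist 1302/1318, 16 cm^-1).
.bandHalfwidth <- function(center) {
  if (center %in% c(1247, 1269)) return(10)
  if (center %in% c(1302, 1318)) return(8)
  20
}

# Locate the peak and flanking troughs for a band window. Returns NULL when
# the window has no interior maximum (monotone segment).
.troughBounds <- function(y, grid, center, halfwidth) {
  n <- length(y)
  win <- which(abs(grid - center) <= halfwidth)
  if (!length(win) || win[1] < 1 || win[length(win)] > n)
    stop("band window at ", center, " cm^-1 outside the grid")
  bound <- which(abs(grid - center) <= 2 * halfwidth)
  lo <- bound[1]; hi <- bound[length(bound)]
  pk <- win[which.max(y[win])]
  # light smoothing for trough detection only; integration uses raw values
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  if ((pk == win[1] || pk == win[length(win)]) &&
      (all(diff(y[win]) >= 0) || all(diff(y[win]) <= 0)))
    return(NULL)
  # walk outward with hysteresis: follow the descent, tracking the running
  # minimum, and stop once the smoothed signal rises a small fraction of
  # the local range above it (so residual noise does not truncate the walk)
  # hysteresis threshold: a fraction of the local dynamic range, floored at
  # a robust estimate of the residual noise on the smoothed trace
  eps <- max(0.08 * diff(range(ys[lo:hi])),
             2.5 * stats::mad(diff(ys[lo:hi])))
  walk <- function(from, to, step) {
    run_min <- ys[from]; run_pos <- from
    i <- from
    while (i != to) {
      i <- i + step
      if (ys[i] < run_min) { run_min <- ys[i]; run_pos <- i }
      else if (ys[i] > run_min + eps) break
    }
    run_pos
  }
  pk_s <- win[which.max(ys[win])]   # walk from the smoothed peak
  l <- walk(pk_s, lo, -1L)
  r <- walk(pk_s, hi, 1L)
  if (r - l < 2 || pk <= l || pk >= r)
    return(NULL)  # no flanked peak (noise pip or plateau)
  list(peak = pk, left = l, right = r)
}

# The straight line joining the two troughs, evaluated at `at`.
.troughLine <- function(y, grid, tb, at) {
  slope <- (y[tb$right] - y[tb$left]) / (grid[tb$right] - grid[tb$left])
  y[tb$left] + slope * (at - grid[tb$left])
}

#' Trough-baseline band area
#'
#' Integrates a band above a local linear baseline: the channel of maximum
#' intensity within `center +/- halfwidth` is located, the nearest local
#' minima (troughs) on each side are found by walking outward (bounded by
#' `center +/- 2*halfwidth`), the straight line joining the two troughs is
#' subtracted, and the positive part is integrated by the trapezoidal rule.
#' Trough detection runs on a lightly smoothed copy (5-channel moving
#' average) to avoid noise minima; integration uses raw intensities.
#'
#' @param x baseline-corrected, normalized numeric spectrum or a
#'   [RamanSpectra-class] (areas computed per column).
#' @param center band center (cm^-1).
#' @param grid wavenumber grid (numeric input only).
#' @param halfwidth search half-width (cm^-1). The default (`NULL`) is 20,
#'   narrowed to 10 for the amide III sub-peaks (1247/1269) and 8 for the
#'   CH2-twist doublet (1302/1318) so that close doublet neighbours stay
#'   outside the search window.
#' @return band area (intensity x cm^-1); 0 with a warning when the window
#'   is monotone. Vector for `RamanSpectra` input.
#' @examples
#' g <- wavenumberGrid(n_channels = 1780)
#' y <- exp(-(g - 1003)^2 / (2 * 25))  # sigma = 5
#' bandArea(y, 1003, grid = g)         # ~ 5 * sqrt(2*pi) = 12.53
#' @export
bandArea <- function(x, center, grid = NULL, halfwidth = NULL) {
  if (is.null(halfwidth)) halfwidth <- .bandHalfwidth(center)
  if (is(x, "RamanSpectra")) {
    Y <- assay(x, "intensity")
    g <- wavenumbers(x)
    return(vapply(seq_len(ncol(Y)),
                  function(j) bandArea(Y[, j], center, g, halfwidth),
                  numeric(1)))
  }
  if (is.null(grid)) grid <- wavenumberGrid(n_channels = length(x))
  tb <- .troughBounds(x, grid, center, halfwidth)
  if (is.null(tb)) {
    warning("no interior maximum near ", center, " cm^-1; area set to 0")
    return(0)
  }
  idx <- tb$left:tb$right
  base <- .troughLine(x, grid, tb, grid[idx])
  h <- pmax(x[idx] - base, 0)  # negative excursions clipped
  sum(diff(grid[idx]) * (h[-1] + h[-length(h)]) / 2)
}

#' Trough-baseline peak height
#'
#' Height of the band maximum above the trough-to-trough line used by
#' [bandArea()]; never negative.
#'
#' @inheritParams bandArea
#' @return peak height (intensity units); 0 when the window is monotone.
#' @export
peakHeight <- function(x, center, grid = NULL, halfwidth = NULL) {
  if (is.null(halfwidth)) halfwidth <- .bandHalfwidth(center)
  if (is(x, "RamanSpectra")) {
    Y <- assay(x, "intensity")
    g <- wavenumbers(x)
    return(vapply(seq_len(ncol(Y)),
                  function(j) peakHeight(Y[, j], center, g, halfwidth),
                  numeric(1)))
  }
  if (is.null(grid)) grid <- wavenumberGrid(n_channels = length(x))
  tb <- .troughBounds(x, grid, center, halfwidth)
  if (is.null(tb)) return(0)
  base <- .troughLine(x, grid, tb, grid[tb$peak])
  max(x[tb$peak] - base, 0)
}
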