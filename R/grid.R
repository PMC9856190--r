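#' Wavenumber grid
#'
#' The shared Raman-shift axis: a uniform grid of `n_channels` channels from
#' `start` to `stop` cm^-1. The default (500-2000 cm^-1, 1780 channels)
#' matches the acquisition convention used throughout the package, in which
#' the 12 polarized spectra of a detection point form a 12 x 1780 matrix.
#'
#' @param start,stop grid limits in cm^-1.
#' @param n_channels number of channels.
#' @return numeric vector of wavenumbers, strictly increasing, uniform.
#' @examples
#' g <- wavenumberGrid()
#' length(g)  # 1780
#' @export
wavenumberGrid <- function(start = 500, stop = 2000, n_channels = 1780) {
  if (!(is.numeric(start) && is.numeric(stop) && stop > start))
    stop("need stop > start")
  if (n_channels < 2) stop("n_channels must be >= 2")
  seq(start, stop, length.out = n_channels)
}

# Nearest channel index for a target wavenumber.
channelIndex <- function(grid, wavenumber) {
  if (wavenumber < grid[1] || wavenumber > grid[length(grid)])
    stop("wavenumber ", wavenumber, " outside grid range")
  which.min(abs(grid - wavenumber))
}
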