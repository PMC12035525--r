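#' The common wavelength grid
#'
#' All spectra in the package live on a fixed 1-nm grid spanning the solar
#' reflective domain, 400--2500 nm (2101 points). Inputs sampled on other
#' grids are linearly interpolated onto this grid on read.
#'
#' @return Integer vector of wavelengths in nanometres.
#' @export
#' @examples
#' head(spectral_grid())
spectral_grid <- function() {
  400:2500
}

# Number of grid points; used throughout for sanity checks.
n_grid <- function() length(spectral_grid())

#' Interpolate a spectrum onto the common wavelength grid
#'
#' @param wavelength Wavelengths (nm) of the input values, strictly increasing.
#' @param value Values at `wavelength`.
#' @param rule Passed to [stats::approx()]; default 2 extends the endpoint
#'   values so that inputs covering 400--2500 nm only approximately still
#'   yield a full grid.
#' @return Numeric vector on [spectral_grid()].
#' @export
regrid <- function(wavelength, value, rule = 2) {
  if (is.unsorted(wavelength, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  stats::approx(wavelength, value, xout = spectral_grid(), rule = rule)$y
}

# Restrict a full-grid spectrum to a subset of wavelengths (integer nm).
# Used by the inversion machinery to fit on thinned grids for speed.
grid_index <- function(wavelengths) {
  idx <- match(wavelengths, spectral_grid())
  if (anyNA(idx)) {
    stop("wavelengths must be integers within 400-2500 nm", call. = FALSE)
  }
  idx
}
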