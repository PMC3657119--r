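#' Uniform wavelength grid for spectral modelling
#'
#' All curves in the package (pigment absorbance, droplet transmittance, lamp
#' irradiance) live on a shared uniform wavelength grid. The default window,
#' 200--750 nm at 0.1 nm, covers the full support of A1 visual pigment
#' templates for lambda_max between 300 and 700 nm.
#'
#' @param from,to Window endpoints in nm (`from < to`).
#' @param step Grid step in nm (> 0).
#' @return Numeric vector of strictly increasing, uniformly spaced wavelengths.
#' @examples
#' g <- wavelength_grid()
#' length(g)
#' @export
wavelength_grid <- function(from = 200, to = 750, step = 0.1) {
  if (!is.numeric(from) || !is.numeric(to) || from >= to) {
    stop("`from` must be smaller than `to`", call. = FALSE)
  }
  if (!is.numeric(step) || step <= 0) {
    stop("`step` must be a positive number of nm", call. = FALSE)
  }
  n <- floor((to - from) / step + 1e-9)
  from + step * (0:n)
}

# step of a uniform grid, with a guard against irregular spacing
grid_step <- function(grid) {
  d <- diff(grid)
  if (any(d <= 0)) stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (max(d) - min(d) > 1e-6) {
    stop("wavelength grid must be uniformly spaced", call. = FALSE)
  }
  mean(d)
}

#' Spectral curve on a wavelength grid
#'
#' Lightweight container pairing a uniform wavelength grid with non-negative
#' curve values. Used for pigment absorbance (peak-normalized to 1), oil
#' droplet transmittance (values in \[0, 1\]) and resampled lamp irradiance.
#'
#' @param wavelength Strictly increasing, uniformly spaced wavelengths (nm).
#' @param value Numeric values, same length, all finite and >= 0.
#' @return An object of class `spectral_curve`.
#' @export
spectral_curve <- function(wavelength, value) {
  if (length(wavelength) != length(value)) {
    stop("`wavelength` and `value` must have the same length", call. = FALSE)
  }
  grid_step(wavelength)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("curve values must be finite and non-negative", call. = FALSE)
  }
  structure(list(wavelength = wavelength, value = value), class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf(
    "<spectral_curve> %d points, %.1f-%.1f nm @ %.3g nm, max value %.4g\n",
    length(x$wavelength), min(x$wavelength), max(x$wavelength),
    grid_step(x$wavelength), max(x$value)
  ))
  invisible(x)
}

stopifnot_same_grid <- function(a, b) {
  if (length(a$wavelength) != length(b$wavelength) ||
      max(abs(a$wavelength - b$wavelength)) > 1e-9) {
    stop("curves are defined on different wavelength grids", call. = FALSE)
  }
  invisible(TRUE)
}
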