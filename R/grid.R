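#' Wavelength grid with half-open bins
#'
#' Defines the common discretization used by every spectral quantity in the
#' package: contiguous half-open bins `[lambda_k, lambda_k + step)` of equal
#' width. All tabulated optical properties are resolved onto the bin centers
#' and treated as piecewise constant within a bin during photon transport.
#'
#' @param min_nm lower edge of the first bin (nm)
#' @param max_nm upper edge of the last bin (nm)
#' @param step_nm bin width (nm), must divide `max_nm - min_nm`
#' @return an object of class `fc_grid` with fields `edges`, `centers`,
#'   `step`, `n_bins`
#' @examples
#' g <- spectral_grid(350, 800, 1)
#' g$n_bins
#' @export
spectral_grid <- function(min_nm = 350, max_nm = 800, step_nm = 1) {
  stopifnot(is.numeric(min_nm), is.numeric(max_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("bin width must be positive")
  if (max_nm <= min_nm) stop("max_nm must exceed min_nm")
  n <- (max_nm - min_nm) / step_nm
  if (abs(n - round(n)) > 1e-9) stop("step_nm must divide the grid range")
  n <- as.integer(round(n))
  edges <- min_nm + step_nm * (0:n)
  structure(
    list(edges = edges, centers = edges[-(n + 1L)] + step_nm / 2,
         step = step_nm, n_bins = n),
    class = "fc_grid")
}

#' @export
print.fc_grid <- function(x, ...) {
  cat(sprintf("<fc_grid> %g-%g nm, %d bins of %g nm\n",
              x$edges[1], x$edges[length(x$edges)], x$n_bins, x$step))
  invisible(x)
}

#' Bin index of a wavelength
#'
#' Half-open convention: `lambda` belongs to bin `k` iff
#' `edges[k] <= lambda < edges[k+1]`. Wavelengths outside the grid return NA.
#'
#' @param grid an `fc_grid`
#' @param lambda numeric vector of wavelengths (nm)
#' @return integer bin indices (1-based), NA outside the grid
#' @export
grid_bin <- function(grid, lambda) {
  k <- floor((lambda - grid$edges[1]) / grid$step) + 1L
  k[lambda < grid$edges[1] | lambda >= grid$edges[length(grid$edges)]] <- NA_integer_
  as.integer(k)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$edges, b$edges, tolerance = 1e-12))
}

#' Spectrum on a wavelength grid
#'
#' A spectrum is a vector of radiant power (or dimensionless weight) per
#' wavelength bin, attached to the grid it lives on.
#'
#' @param grid an `fc_grid`
#' @param values numeric vector of length `grid$n_bins` (a scalar is
#'   recycled)
#' @return an object of class `fc_spectrum`
#' @export
spectrum <- function(grid, values) {
  stopifnot(inherits(grid, "fc_grid"))
  values <- as.numeric(values)
  if (length(values) == 1L) values <- rep(values, grid$n_bins)
  if (length(values) != grid$n_bins)
    stop("values length must equal the number of grid bins")
  if (any(!is.finite(values))) stop("spectrum values must be finite")
  structure(list(grid = grid, values = values), class = "fc_spectrum")
}

#' @export
print.fc_spectrum <- function(x, ...) {
  cat(sprintf("<fc_spectrum> %d bins, total %.6g, peak %.6g at %.1f nm\n",
              x$grid$n_bins, sum(x$values) * x$grid$step,
              max(x$values), x$grid$centers[which.max(x$values)]))
  invisible(x)
}

#' Integral of a spectrum over wavelength
#' @param s an `fc_spectrum`
#' @return `sum(values) * bin width`
#' @export
spectrum_integral <- function(s) sum(s$values) * s$grid$step

#' Intensity-weighted mean wavelength of a spectrum
#' @param s an `fc_spectrum`
#' @return mean wavelength in nm (NA for an all-zero spectrum)
#' @export
spectrum_mean_wavelength <- function(s) {
  tot <- sum(s$values)
  if (tot <= 0) return(NA_real_)
  sum(s$grid$centers * s$values) / tot
}

#' Gaussian source spectrum
#'
#' Convenience constructor for a band-limited excitation source: a Gaussian
#' line of given center and full width at half maximum, sampled on the grid.
#'
#' @param grid an `fc_grid`
#' @param center_nm line center (nm)
#' @param fwhm_nm full width at half maximum (nm)
#' @param power total integrated power (arbitrary units)
#' @return an `fc_spectrum`
#' @export
gaussian_source <- function(grid, center_nm, fwhm_nm, power = 1) {
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  v <- stats::dnorm(grid$centers, center_nm, sigma)
  s <- sum(v) * grid$step
  if (s <= 0) stop("source has no support on the grid")
  spectrum(grid, v * power / s)
}
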