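#' Default Rhodamine-6G-like intrinsic emission truth
#'
#' A three-component mixture emulating the shape of a Rhodamine 6G emission
#' band: a dominant narrow peak near 555 nm, a shoulder near 585 nm, and a
#' weak red tail. Used as the generating truth of the synthetic fixtures.
#'
#' @param support truncation interval (nm); default `c(500, 800)`
#' @return an `fc_emission_gmm`
#' @export
default_emission_truth <- function(support = c(500, 800)) {
  emission_gmm(means = c(555, 585, 625), sigmas = c(12, 20, 35),
               weights = c(0.55, 0.33), support = support)
}

#' Synthetic Rhodamine-like fluorophore component
#'
#' A fluorescent component with a Gaussian absorption band overlapping the
#' blue edge of the emission distribution (the configuration that drives the
#' re-absorption cascade), negligible scattering, and a configured quantum
#' yield. The `zero_overlap` variant places the absorption band strictly
#' below the emission support (absorption set to exactly zero on the
#' support), so escaping fluorescence can never be re-absorbed.
#'
#' @param grid an `fc_grid`
#' @param peak_mu_a peak absorption coefficient (per mm) at reference
#'   concentration (weight 1)
#' @param abs_peak_nm,abs_width_nm center and standard deviation of the
#'   absorption band
#' @param phi_f quantum yield (default 0.9, Rhodamine-like)
#' @param emission intrinsic emission model; default
#'   [default_emission_truth()]
#' @param zero_overlap construct the no-re-absorption variant
#' @param name component name
#' @return an `fc_component`
#' @export
make_fluorophore <- function(grid, peak_mu_a = 0.5, abs_peak_nm = 527,
                             abs_width_nm = 22, phi_f = 0.9,
                             emission = NULL, zero_overlap = FALSE,
                             name = "fluorophore") {
  if (zero_overlap) {
    emission <- if (is.null(emission))
      default_emission_truth(support = c(520, 800)) else emission
    abs_peak_nm <- 450; abs_width_nm <- 15
  } else if (is.null(emission)) {
    emission <- default_emission_truth()
  }
  mu_a <- peak_mu_a * exp(-(grid$centers - abs_peak_nm)^2 / (2 * abs_width_nm^2))
  if (zero_overlap) mu_a[grid$centers >= emission$support[1]] <- 0
  optical_component(name, grid, mu_a = mu_a, mu_s = 0, g = 0,
                    is_fluorescent = TRUE, phi_f = phi_f, emission = emission)
}

#' Synthetic microsphere scatterer component
#'
#' Non-absorbing forward scatterer with a power-law spectral slope:
#' `mu_s(lambda) = mu_s(lambda0) (lambda/lambda0)^(-slope)`, where
#' `mu_s(lambda0)` is set so the reduced scattering coefficient
#' `mu_s' = mu_s (1 - g)` hits the requested target at the anchor
#' wavelength.
#'
#' @param grid an `fc_grid`
#' @param mus_prime_target reduced scattering coefficient (per mm) at
#'   `lambda0_nm`
#' @param g Henyey-Greenstein anisotropy (constant over the grid)
#' @param lambda0_nm anchor wavelength (nm)
#' @param slope spectral power-law exponent (0 = flat)
#' @param name component name
#' @return an `fc_component`
#' @export
make_scatterer <- function(grid, mus_prime_target = 12, g = 0.9,
                           lambda0_nm = 550, slope = 1,
                           name = "scatterer") {
  if (abs(g) >= 1) stop("anisotropy g must lie in (-1, 1)")
  mus0 <- mus_prime_target / (1 - g)
  mu_s <- mus0 * (grid$centers / lambda0_nm)^(-slope)
  optical_component(name, grid, mu_a = 0, mu_s = mu_s, g = g)
}

#' Weakly absorbing non-fluorescent solvent/matrix component
#' @param grid an `fc_grid`
#' @param mu_a absorption (per mm), scalar or vector
#' @param name component name
#' @return an `fc_component`
#' @export
make_solvent <- function(grid, mu_a = 0.01, name = "solvent") {
  optical_component(name, grid, mu_a = mu_a, mu_s = 0, g = 0)
}

#' Glass-plate cuvette stack around a medium layer
#'
#' The reference cuvette: two 1 mm glass plates (BK7-like, n = 1.5168,
#' non-scattering, non-absorbing) separated by a 4 mm spacer holding the
#' medium, air on both outsides. The `index_matched` variant sets every
#' index (plates, medium, ambient) equal, removing all boundary reflections
#' for analytic tests.
#'
#' @param components named list of medium components (`fc_component`)
#' @param weights named concentration weights of the medium mixture
#' @param n_medium refractive index of the medium (ethanol-like default
#'   1.36; PDMS-like 1.41)
#' @param medium_thickness_mm spacer thickness (default 4)
#' @param glass_thickness_mm plate thickness (default 1)
#' @param n_glass plate index (default 1.5168)
#' @param glass logical: include the plates (default TRUE)
#' @param index_matched logical: set all indices to `n_medium` and ambient
#'   likewise
#' @return an `fc_sample`
#' @export
make_cuvette <- function(components, weights, n_medium = 1.36,
                         medium_thickness_mm = 4, glass_thickness_mm = 1,
                         n_glass = 1.5168, glass = TRUE,
                         index_matched = FALSE) {
  grid <- components[[1]]$grid
  reg <- components
  if (glass) reg$glass <- optical_component("glass", grid, mu_a = 0)
  if (index_matched) n_glass <- n_medium
  n_amb <- if (index_matched) n_medium else 1
  medium <- list(thickness_mm = medium_thickness_mm, n = n_medium,
                 components = weights)
  layers <- if (glass) {
    plate <- list(thickness_mm = glass_thickness_mm, n = n_glass,
                  components = c(glass = 1))
    list(plate, medium, plate)
  } else list(medium)
  layered_sample(layers, reg, n_above = n_amb, n_below = n_amb)
}

#' Preset synthetic samples
#'
#' Deterministic sample fixtures emulating the reference measurements:
#' \describe{
#'   \item{`ethanol-c1` / `ethanol-c2` / `ethanol-c3`}{dye in an
#'     ethanol-like medium (n = 1.36) with microsphere scatterers, in the
#'     glass cuvette; dye concentration weights 1 : 2 : 4.}
#'   \item{`pdms-a` / `pdms-b`}{dye in a PDMS-like matrix (n = 1.41) with
#'     strong scattering and a lower quantum yield (0.75); concentration
#'     weights 2 : 1.}
#'   \item{`zero-overlap`}{index-matched non-scattering slab whose
#'     absorption band lies strictly below the emission support (no
#'     re-absorption possible).}
#'   \item{`bare-dye`}{index-matched, non-scattering, glass-free dye slab
#'     with overlapping bands: the cleanest cascade configuration for
#'     analytic comparisons.}
#'   \item{`red-edge`}{like `bare-dye` but with a strong absorption band
#'     overlapping only the short-wavelength side of the emission
#'     (absorption peak 545 nm, width 25 nm, peak 1 per mm): the cascade
#'     diagnostics fixture, producing a pronounced per-cycle red shift.}
#' }
#' The scattering level is configurable because the full reference level
#' (`mu_s' ~ 12` per mm) makes CPU transport diffusive and slow; presets
#' default to a light-scattering variant suitable for test budgets.
#'
#' @param grid an `fc_grid` (default 1 nm bins over 350-800 nm)
#' @param preset preset name
#' @param phi_f quantum yield override (defaults per preset)
#' @param mus_prime reduced scattering (per mm) for the scattering presets
#' @return an `fc_sample`
#' @export
make_fixture_sample <- function(grid = spectral_grid(),
                                preset = c("ethanol-c3", "ethanol-c2",
                                           "ethanol-c1", "pdms-a", "pdms-b",
                                           "zero-overlap", "bare-dye",
                                           "red-edge"),
                                phi_f = NULL, mus_prime = 0.5) {
  preset <- match.arg(preset)
  if (preset %in% c("zero-overlap", "bare-dye", "red-edge")) {
    if (is.null(phi_f)) phi_f <- 0.9
    dye <- if (preset == "red-edge")
      make_fluorophore(grid, peak_mu_a = 1, abs_peak_nm = 545,
                       abs_width_nm = 25, phi_f = phi_f)
    else make_fluorophore(grid, phi_f = phi_f,
                          zero_overlap = preset == "zero-overlap")
    return(make_cuvette(list(fluorophore = dye), c(fluorophore = 1),
                        glass = FALSE, index_matched = TRUE))
  }
  conc <- switch(preset, "ethanol-c1" = 1, "ethanol-c2" = 2,
                 "ethanol-c3" = 4, "pdms-a" = 2, "pdms-b" = 1)
  pdms <- grepl("^pdms", preset)
  if (is.null(phi_f)) phi_f <- if (pdms) 0.75 else 0.9
  dye <- make_fluorophore(grid, phi_f = phi_f)
  sc <- make_scatterer(grid, mus_prime_target = mus_prime)
  sol <- make_solvent(grid, mu_a = 0.005)
  make_cuvette(list(fluorophore = dye, scatterer = sc, solvent = sol),
               c(fluorophore = conc, scatterer = 1, solvent = 1),
               n_medium = if (pdms) 1.41 else 1.36)
}

#' Default excitation source for the fixtures
#'
#' Band-limited Gaussian line centered on the fixture absorption band.
#' @param grid an `fc_grid`
#' @param center_nm,fwhm_nm line parameters (defaults 510 / 10 nm)
#' @param power integrated power
#' @return an `fc_spectrum`
#' @export
make_fixture_source <- function(grid, center_nm = 510, fwhm_nm = 10,
                                power = 1) {
  gaussian_source(grid, center_nm, fwhm_nm, power)
}

#' Synthetic sphere-detected measurement with known truth
#'
#' Runs the full forward twin at a known quantum yield and emission model
#' and perturbs each detected bin with multiplicative Gaussian noise of the
#' stated relative level. The generating truth is recorded alongside so
#' recovery experiments can compare against it. Bit-reproducible from
#' `(inputs, seed)`; noise uses a derived stream that does not disturb the
#' caller's RNG state.
#'
#' @param sample an `fc_sample` (carrying the truth `phi_f` and emission)
#' @param source an `fc_spectrum`
#' @param geometry an `fc_sphere` or per-side list
#' @param n_photons photons for the forward run
#' @param seed RNG seed
#' @param noise_rel relative noise level (default 0.01)
#' @param irf optional `fc_irf`
#' @return list with `reflectance`, `transmission` (noisy `fc_spectrum`s),
#'   `truth` (`phi_f`, `gmm`), and `noise_rel`
#' @export
make_synthetic_measurement <- function(sample, source, geometry, n_photons,
                                       seed, noise_rel = 0.01, irf = NULL) {
  sim <- simulate_detected_spectra(sample, source, geometry, n_photons,
                                   seed, irf = irf)
  fluor <- NULL
  for (cm in sample$components) if (cm$is_fluorescent) { fluor <- cm; break }
  if (is.null(fluor)) stop("sample has no fluorescent component")
  add_noise <- function(spec, stream) {
    if (noise_rel == 0) return(spec)
    u <- cpp_stream_uniforms(2 * spec$grid$n_bins, seed * 1000003 + stream)
    z <- stats::qnorm(pmin(pmax(u[seq_len(spec$grid$n_bins)], 1e-12),
                           1 - 1e-12))
    spectrum(spec$grid, pmax(spec$values * (1 + noise_rel * z), 0))
  }
  list(reflectance = add_noise(sim$reflectance, 1),
       transmission = add_noise(sim$transmission, 2),
       truth = list(phi_f = fluor$phi_f, gmm = fluor$emission),
       noise_rel = noise_rel)
}
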