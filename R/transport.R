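#' @useDynLib fluocascade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Run the forward fluorescence cascade simulation
#'
#' Traces `n_photons` photons through a layered sample, resolving the full
#' re-absorption/re-emission cascade: exponential free paths from the total
#' extinction coefficient, analog absorption-vs-scattering decisions,
#' component selection by cumulative coefficient fractions,
#' Bernoulli(`phi_f`) re-emission with isotropic direction and a new
#' wavelength from the component's intrinsic emission distribution,
#' Henyey-Greenstein scattering, and unpolarized Fresnel/Snell boundaries.
#' Photon weights carry only the Stokes factor `lambda_old / lambda_new`
#' per conversion, so every escaping photon's weight equals
#' `lambda_launch / lambda_exit` exactly and integer photon conservation
#' (`launched = escaped + terminally absorbed`) holds on every run.
#'
#' Results are bit-reproducible for a fixed `(seed, n_photons)`: each photon
#' runs on its own counter-seeded RNG stream.
#'
#' @param sample an `fc_sample`
#' @param source an `fc_spectrum`, the excitation spectrum (must be on the
#'   sample grid); ignored when `launch_wavelength = "stratified"`
#' @param n_photons number of photons to launch
#' @param seed non-negative integer seed
#' @param beam `"pencil"` (collimated, normal incidence; default) or
#'   `"cosine"` (diffuse cosine-distributed incidence, used by the
#'   integrating-sphere auxiliary reflectance run)
#' @param launch_wavelength `"source"` (inverse-CDF sampling of `source`) or
#'   `"stratified"` (photon `i` launched uniformly inside bin
#'   `i mod n_bins`, for per-wavelength response maps)
#' @param collect_records keep the per-photon exit record matrix (needed by
#'   the sphere twin and cascade diagnostics; disable to save memory)
#' @return an object of class `fc_tallies`: reflectance/transmission weight
#'   spectra, the exit record matrix (`side` 0 = reflectance, 1 =
#'   transmission; positions mm; direction cosines; `lambda`, `weight`,
#'   `n_cycles`, `lambda_launch`), the per-component absorption ledger, and
#'   integer event counters
#' @export
run_forward <- function(sample, source, n_photons, seed,
                        beam = c("pencil", "cosine"),
                        launch_wavelength = c("source", "stratified"),
                        collect_records = TRUE) {
  stopifnot(inherits(sample, "fc_sample"))
  beam <- match.arg(beam)
  launch_wavelength <- match.arg(launch_wavelength)
  grid <- sample$grid
  if (launch_wavelength == "source") {
    stopifnot(inherits(source, "fc_spectrum"))
    if (!grids_identical(source$grid, grid))
      stop("source spectrum is not on the sample grid")
    tot <- sum(source$values)
    if (tot <= 0) stop("source spectrum has zero power")
    src_cdf <- c(0, cumsum(source$values)) / tot
  } else {
    src_cdf <- seq(0, 1, length.out = grid$n_bins + 1L)
  }
  if (n_photons < 1) stop("n_photons must be at least 1")
  if (seed < 0) stop("seed must be non-negative")

  res <- resolve_sample(sample)
  out <- cpp_mc_run(res, src_cdf,
                    launch_geom = if (beam == "cosine") 1L else 0L,
                    launch_wavelength = if (launch_wavelength == "stratified") 1L else 0L,
                    n_photons = as.double(n_photons), seed = as.double(seed),
                    collect_records = collect_records)
  if (out$n_stuck > 0)
    warning(out$n_stuck, " photon(s) terminated by the step guard")
  if (out$n_launched != out$n_escaped + out$n_terminated)
    stop(sprintf("photon conservation violated: %d launched, %d escaped, %d absorbed",
                 out$n_launched, out$n_escaped, out$n_terminated))

  ledger <- data.frame(component = res$comp_names,
                       is_fluorescent = as.logical(res$is_fluo),
                       n_abs_primary = out$n_abs_primary,
                       n_abs_secondary = out$n_abs_secondary,
                       w_abs_primary = out$w_abs_primary,
                       w_abs_secondary = out$w_abs_secondary,
                       n_emit = out$n_emit,
                       n_terminal = out$n_term,
                       stringsAsFactors = FALSE)
  structure(list(
    grid = grid,
    reflectance = spectrum(grid, out$refl),
    transmission = spectrum(grid, out$trans),
    launch_counts = out$launch_w,
    refl_by_launch = out$refl_by_launch,
    trans_by_launch = out$trans_by_launch,
    records = out$records,
    absorption_ledger = ledger,
    launched = out$n_launched,
    escaped = out$n_escaped,
    terminally_absorbed = out$n_terminated,
    n_exit_fluorescent = out$n_exit_fluorescent,
    seed = seed, beam = beam), class = "fc_tallies")
}

#' @export
print.fc_tallies <- function(x, ...) {
  cat(sprintf("<fc_tallies> %d launched: %d escaped, %d absorbed\n",
              x$launched, x$escaped, x$terminally_absorbed))
  cat(sprintf("  reflectance weight %.5g, transmission weight %.5g\n",
              sum(x$reflectance$values), sum(x$transmission$values)))
  invisible(x)
}

#' Quantum-yield estimators from simulation tallies
#'
#' Three photon-count ratios that an integrating-sphere protocol could
#' report:
#' \describe{
#'   \item{`intrinsic_def`}{re-emission events divided by all absorption
#'     events in fluorescent components: the defining ratio of emitted to
#'     absorbed photons, which converges to the configured quantum yield.}
#'   \item{`uncorrected`}{escaping wavelength-converted photons divided by
#'     primary absorption events (first absorption of a source photon) in
#'     fluorescent components: what a sphere measurement reports when the
#'     re-absorption cascade is ignored. Biased low whenever absorption and
#'     emission bands overlap.}
#'   \item{`gross`}{same numerator divided by primary absorption events in
#'     any component, fluorescent or not: the further-biased estimate
#'     obtained when absorption sites are not differentiated.}
#' }
#'
#' @param tallies an `fc_tallies`
#' @param mode one of `"intrinsic_def"`, `"uncorrected"`, `"gross"`
#' @return the requested ratio
#' @export
estimate_quantum_yield <- function(tallies,
                                   mode = c("intrinsic_def", "uncorrected",
                                            "gross")) {
  mode <- match.arg(mode)
  led <- tallies$absorption_ledger
  fl <- led$is_fluorescent
  num_den <- switch(mode,
    intrinsic_def = c(sum(led$n_emit),
                      sum(led$n_abs_primary[fl] + led$n_abs_secondary[fl])),
    uncorrected = c(tallies$n_exit_fluorescent, sum(led$n_abs_primary[fl])),
    gross = c(tallies$n_exit_fluorescent, sum(led$n_abs_primary)))
  if (num_den[2] == 0) stop("zero absorption events: quantum yield undefined")
  num_den[1] / num_den[2]
}

# ----------------------------------------------------------------------
# Elementary transport operations, exposed for inspection and testing.
# The production path is the compiled kernel; these mirror its physics.
# ----------------------------------------------------------------------

#' Exponential free-path sampling
#'
#' `s = -log(1 - xi) / mu_t`; a vanishing extinction coefficient gives an
#' unbounded path (the photon travels to the next boundary).
#'
#' @param mu_t total extinction coefficient (per mm), >= 0
#' @param xi uniform variates in `[0, 1)`
#' @return path lengths (mm)
#' @export
sample_free_path <- function(mu_t, xi) {
  if (mu_t < 0) stop("mu_t must be non-negative")
  if (mu_t == 0) return(rep(Inf, length(xi)))
  -log1p(-xi) / mu_t
}

#' Absorption-vs-scattering decision at an interaction site
#'
#' @param mu_a_tot,mu_s_tot total absorption / scattering coefficients (per
#'   mm) at the interaction wavelength; their sum must be positive
#' @param xi uniform variate
#' @return `"absorb"` iff `xi < mu_a_tot / (mu_a_tot + mu_s_tot)`, else
#'   `"scatter"`
#' @export
choose_interaction <- function(mu_a_tot, mu_s_tot, xi) {
  if (mu_a_tot + mu_s_tot <= 0) stop("both coefficients are zero")
  ifelse(xi < mu_a_tot / (mu_a_tot + mu_s_tot), "absorb", "scatter")
}

#' Henyey-Greenstein deflection cosine
#'
#' Analytic inverse-CDF sample of the scattering deflection:
#' `cos(theta) = (1 + g^2 - ((1 - g^2) / (1 - g + 2 g xi))^2) / (2 g)` for
#' `g != 0`, and `2 xi - 1` in the isotropic limit.
#'
#' @param g anisotropy in (-1, 1)
#' @param xi uniform variates
#' @return deflection cosines
#' @export
sample_hg_cosine <- function(g, xi) {
  if (abs(g) >= 1) stop("anisotropy g must lie in (-1, 1)")
  vapply(xi, function(u) cpp_hg_cos(g, u), 0)
}

#' Unpolarized Fresnel reflectance
#'
#' Mean of the s- and p-polarized power reflectances for a ray crossing from
#' index `n1` to `n2` at incidence cosine `cos_i`; returns 1 beyond the
#' critical angle (total internal reflection).
#'
#' @param n1,n2 refractive indices (> 0)
#' @param cos_i cosine of the incidence angle, in (0, 1]
#' @return reflectance in `[0, 1]`
#' @export
fresnel_reflectance <- function(n1, n2, cos_i) {
  vapply(cos_i, function(ci) cpp_fresnel(n1, n2, ci), 0)
}

#' Boundary interaction: specular reflection or Snell refraction
#'
#' @param direction unit direction vector (length 3), `z` component nonzero
#' @param n1,n2 indices on the incident / far side
#' @param xi uniform variate deciding reflection (`xi <` Fresnel R)
#' @return list with `direction` (unit vector) and `crossed` (logical)
#' @export
boundary_interaction <- function(direction, n1, n2, xi) {
  u <- direction / sqrt(sum(direction^2))
  R <- cpp_fresnel(n1, n2, abs(u[3]))
  if (xi < R) {
    return(list(direction = c(u[1], u[2], -u[3]), crossed = FALSE))
  }
  eta <- n1 / n2
  st2 <- eta^2 * (1 - u[3]^2)
  ct <- sqrt(max(0, 1 - st2))
  v <- c(u[1] * eta, u[2] * eta, sign(u[3]) * ct)
  list(direction = v / sqrt(sum(v^2)), crossed = TRUE)
}

#' One absorption event with possible fluorescent re-emission
#'
#' Reference implementation of the absorption subroutine acting on a single
#' photon state: the absorbing component is chosen by cumulative absorption
#' fractions, non-fluorescent absorption (or a Bernoulli failure against
#' `phi_f`) terminates the photon, and otherwise a new wavelength is drawn
#' from the component's emission distribution, the weight is multiplied by
#' `lambda_old / lambda_new`, the direction is reset isotropically, and the
#' cycle counter is incremented.
#'
#' @param photon list with `lambda`, `weight`, `direction`, `n_cycles`
#' @param coeffs output of [mixture_coefficients()] at the photon wavelength
#' @param components the sample's component registry
#' @param xi0,xi1,xi2,xi3,xi_lambda uniform variates: component choice,
#'   survival test, two direction angles, emission wavelength
#' @return the photon with `alive = FALSE` and `absorbed_in` set, or the
#'   re-emitted photon (`alive = TRUE`)
#' @export
absorb_or_fluoresce <- function(photon, coeffs, components,
                                xi0, xi1, xi2, xi3, xi_lambda) {
  mu <- c(base = coeffs$mu_a_base, coeffs$mu_a_fluo)
  tot <- sum(mu)
  if (tot <= 0) stop("no absorption at this wavelength")
  pick <- names(mu)[findInterval(xi0 * tot, cumsum(mu),
                                 left.open = TRUE) + 1L]
  if (pick == "base") {
    photon$alive <- FALSE; photon$absorbed_in <- "base"
    return(photon)
  }
  comp <- components[[pick]]
  if (comp$phi_f < 0 || comp$phi_f > 1) stop("phi_f outside [0, 1]")
  if (xi1 > comp$phi_f) {
    photon$alive <- FALSE; photon$absorbed_in <- pick
    return(photon)
  }
  lam_new <- sample_emission(comp$emission, xi_lambda)
  photon$weight <- photon$weight * photon$lambda / lam_new
  photon$lambda <- lam_new
  ct <- 1 - 2 * xi2
  st <- sqrt(max(0, 1 - ct^2))
  phi <- 2 * pi * xi3
  photon$direction <- c(st * cos(phi), st * sin(phi), ct)
  photon$n_cycles <- photon$n_cycles + 1L
  photon$alive <- TRUE
  photon
}
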