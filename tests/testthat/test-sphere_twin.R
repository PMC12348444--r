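test_that("irradiation split conserves weight and classifies exits", {
  g <- test_grid(2)
  geo <- sphere_geometry()
  s <- make_fixture_sample(g, "ethanol-c3")
  t <- run_forward(s, make_fixture_source(g), 5e4, seed = 21)
  recs <- t$records[t$records[, "side"] == 1, , drop = FALSE]
  sp <- irradiation_split(recs, geo, g)
  assigned <- sum(sp$phi_d0$values) + sum(sp$lost$values) +
    sum(vapply(sp$surfaces, function(x) sum(x$values), 0))
  expect_equal(assigned, sum(recs[, "weight"]), tolerance = 1e-12)
  # ballistic source photons of a clear sample travel along +z into the
  # plugged opposing port, a coated surface in the diffuse series
  void <- optical_component("void", g, mu_a = 0)
  vac <- layered_sample(list(list(thickness_mm = 4, n = 1,
                                  components = c(void = 1))),
                        list(void = void))
  tv <- run_forward(vac, make_fixture_source(g), 5e3, seed = 21)
  spv <- irradiation_split(tv$records[tv$records[, "side"] == 1, ,
                                      drop = FALSE], geo, g)
  k <- grid_bin(g, 510)
  expect_gt(spv$surfaces$reflection$values[k], 0)
  expect_equal(sum(spv$lost$values), 0)
})

test_that("surface weights follow subtended solid angles for isotropic exits", {
  g <- spectral_grid(500, 600, 100)          # single-bin grid
  geo <- sphere_geometry()
  # synthetic isotropic point exits from the port center
  set.seed(31)
  n <- 2e5
  ct <- runif(n); phi <- runif(n, 0, 2 * pi); st <- sqrt(1 - ct^2)
  recs <- cbind(side = 1, x = 0, y = 0, ux = st * cos(phi), uy = st * sin(phi),
                uz = ct, lambda = 550, weight = 1, n_cycles = 0,
                lambda_launch = 550)
  colnames(recs) <- c("side", "x", "y", "ux", "uy", "uz", "lambda",
                      "weight", "n_cycles", "lambda_launch")
  sp <- irradiation_split(recs, geo, g)
  # solid-angle fractions of each cap as seen from the sample port center:
  # cap at angular radius theta_c about axis a, seen from the opposite
  # point; quadrature over the exit hemisphere
  frac_oracle <- function(axis, cos_cap) {
    Ps <- geo$radius_mm * geo$ports$sample$axis
    f <- function(ct_, ph_) {
      st_ <- sqrt(1 - ct_^2)
      d <- cbind(st_ * cos(ph_), st_ * sin(ph_), ct_)  # +z = inward normal
      d <- d[, c(1, 2, 3)] %*% diag(3)
      # inward normal of the default sample port is +z already
      od <- Ps[1] * d[, 1] + Ps[2] * d[, 2] + Ps[3] * d[, 3]
      tt <- -od + sqrt(pmax(od^2 - sum(Ps^2) + geo$radius_mm^2, 0))
      q <- (matrix(Ps, nrow(d), 3, byrow = TRUE) + d * tt) / geo$radius_mm
      (q %*% axis)[, 1] > cos_cap
    }
    # uniform-direction quadrature (isotropic exit = uniform in ct, phi)
    ctq <- seq(0.0005, 0.9995, length.out = 800)
    phq <- seq(0, 2 * pi, length.out = 721)[-721]
    mean(vapply(phq, function(p) mean(f(ctq, rep(p, length(ctq)))), 0))
  }
  tot <- sum(recs[, "weight"])
  # open ports accumulate into "lost" and the plugged opposing port into
  # its own surface: each fraction must match the solid-angle quadrature
  exp_loss <- frac_oracle(geo$ports$normalization$axis,
                          geo$ports$normalization$cos_cap) +
    frac_oracle(geo$ports$detector$axis, geo$ports$detector$cos_cap)
  got_loss <- sum(sp$lost$values) / tot
  expect_lt(abs(got_loss - exp_loss), 3 * sqrt(exp_loss / n) + 5e-4)
  exp_refl <- frac_oracle(geo$ports$reflection$axis,
                          geo$ports$reflection$cos_cap)
  got_refl <- sum(sp$surfaces$reflection$values) / tot
  expect_lt(abs(got_refl - exp_refl), 3 * sqrt(exp_refl / n) + 5e-4)
})

open_port_geometry <- function(wall_rho, det = 6) {
  sphere_geometry(
    wall_rho = wall_rho,
    ports = list(
      sample = list(radius_mm = 12.5, axis = c(0, 0, -1), rho = 0),
      reflection = list(radius_mm = 12.5, axis = c(0, 0, 1), rho = 0),
      normalization = list(radius_mm = 12.5, axis = c(-1, 0, 0), rho = 0),
      detector = list(radius_mm = det, axis = c(1, 0, 0), rho = 0)))
}

test_that("analytic bounce model: closed forms and degenerate cases", {
  g <- spectral_grid(500, 600, 100)
  zero <- spectrum(g, 0)
  one <- spectrum(g, 1)
  geo <- open_port_geometry(0.5)
  # all rho = 0: the direct term passes through unchanged
  out0 <- detected_flux(spectrum(g, 2), list(wall = one),
                        open_port_geometry(0))
  expect_equal(out0$values, 2)
  # single wall surface: geometric series in closed form
  out <- detected_flux(zero, list(wall = one), geo)
  expect_equal(out$values,
               (geo$detector_area_mm2 / geo$area_mm2) * 0.5 /
                 (1 - 0.5 * geo$wall_area_mm2 / geo$area_mm2),
               tolerance = 1e-12)
  # a plugged port joins the loss sum even when never irradiated directly
  geo_plug <- sphere_geometry(wall_rho = 0.5)
  out_plug <- detected_flux(zero, list(wall = one), geo_plug)
  loss_plug <- 0.5 * (geo_plug$wall_area_mm2 +
                        geo_plug$ports$reflection$area_mm2) /
    geo_plug$area_mm2
  expect_equal(out_plug$values,
               (geo_plug$detector_area_mm2 / geo_plug$area_mm2) * 0.5 /
                 (1 - loss_plug), tolerance = 1e-12)
  # non-physical gain rejected
  geo_bad <- open_port_geometry(0.97)
  geo_bad$wall_area_mm2 <- geo_bad$area_mm2 * 1.1
  expect_error(detected_flux(zero, list(wall = one), geo_bad), "gain")
})

test_that("analytic bounce model agrees with brute-force ray tracing", {
  # light version of the acceptance oracle: one configuration, fewer rays
  g <- spectral_grid(500, 600, 100)
  geo <- sphere_geometry(
    wall_rho = 0.95,
    ports = list(
      sample = list(radius_mm = 12.5, axis = c(0, 0, -1), rho = 0),
      reflection = list(radius_mm = 12.5, axis = c(0, 0, 1), rho = 0),
      normalization = list(radius_mm = 12.5, axis = c(-1, 0, 0), rho = 0),
      detector = list(radius_mm = 8, axis = c(1, 0, 0), rho = 0)))
  analytic <- detected_flux(spectrum(g, 0), list(wall = spectrum(g, 1)),
                            geo)$values[1]
  # oracle: unit power diffusely reflected off the wall enters the diffuse
  # field carrying rho_wall; the tracer starts after that first reflection
  brute <- 0.95 * trace_diffuse_detected(geo, n_rays = 1e5, seed = 107)
  expect_lt(abs(analytic - brute), 0.03 * analytic)
})

test_that("source inversions are exact algebraic inverses", {
  g <- test_grid(1)
  geo <- open_port_geometry(0.97)     # calibration: open-port configuration
  phs <- gaussian_source(g, 510, 10)
  zero <- spectrum(g, 0)
  # transmission: forward (wall only, no direct FOV hit) then Eq-10 inverse
  fwd <- detected_flux(zero, list(wall = phs), geo)
  back <- invert_source_transmission(fwd, geo)
  expect_equal(back$values, phs$values, tolerance = 1e-12)
  expect_equal(invert_source_transmission(zero, geo)$values, rep(0, g$n_bins))
  # linearity
  fwd2 <- detected_flux(zero, list(wall = spectrum(g, 2 * phs$values)), geo)
  expect_equal(invert_source_transmission(fwd2, geo)$values, 2 * back$values,
               tolerance = 1e-12)

  # reflectance geometry with a mirror: round trip against the matching
  # forward expression
  geo_m <- open_port_geometry(0.97)
  geo_m$mirror <- list(area_mm2 = 300, rho = 0.85)
  denom <- (1 - 0.97 * geo_m$wall_area_mm2 / geo_m$area_mm2 +
              0.85 * 300 / geo_m$area_mm2)
  fwd_m <- spectrum(g, phs$values * (geo_m$detector_area_mm2 / geo_m$area_mm2) *
                      0.85 / denom)
  back_m <- invert_source_reflectance(fwd_m, geo_m)
  expect_equal(back_m$values, phs$values, tolerance = 1e-12)
  # degenerate mirror (rho = 1, zero area): same structural form as the
  # transmission inversion, with the mirror replacing the wall in the
  # detection role (the formulas differ exactly by the factor rho_wall)
  geo_d <- open_port_geometry(0.97)
  geo_d$mirror <- list(area_mm2 = 0, rho = 1)
  expect_equal(invert_source_reflectance(fwd, geo_d)$values,
               invert_source_transmission(fwd, geo)$values * 0.97,
               tolerance = 1e-12)
  expect_error(invert_source_reflectance(fwd, geo), "mirror")
})

test_that("diffuse sample reflectance: vacuum, absorber, scatterer limits", {
  g <- spectral_grid(500, 600, 20)
  void <- optical_component("void", g, mu_a = 0)
  vac <- layered_sample(list(list(thickness_mm = 4, n = 1,
                                  components = c(void = 1))), list(void = void))
  expect_equal(max(sample_diffuse_reflectance(vac, 2e4, 1)$values), 0)
  # perfectly absorbing index-matched slab returns nothing
  blk <- absorbing_slab(g, mu_a = 1e4, d = 4)
  expect_equal(max(sample_diffuse_reflectance(blk, 2e4, 2)$values), 0)
  # thick non-absorbing scattering slab: reflectance grows toward 1
  sc <- make_scatterer(g, mus_prime_target = 2, g = 0.5, slope = 0)
  rho_d <- vapply(c(2, 10, 40), function(d) {
    s <- layered_sample(list(list(thickness_mm = d, n = 1,
                                  components = c(scatterer = 1))),
                        list(scatterer = sc))
    mean(sample_diffuse_reflectance(s, 2e4, 3)$values)
  }, 0)
  expect_true(all(diff(rho_d) > 0))
  expect_gt(rho_d[3], 0.8)
})

test_that("instrument convolution and deconvolution", {
  g <- test_grid(1)
  irf <- gaussian_irf(g, 3.7)
  expect_equal(sum(irf$kernel), 1, tolerance = 1e-12)
  # delta kernel: identity both ways
  delta <- instrument_function(c(0, 1, 0))
  spec <- gaussian_source(g, 550, 12)
  expect_equal(convolve_instrument(spec, delta)$values, spec$values)
  expect_equal(deconvolve_instrument(spec, delta)$values, spec$values)
  # integral preserved
  two_peak <- spectrum(g, dnorm(g$centers, 540, 4) + 0.7 * dnorm(g$centers, 580, 5))
  blurred <- convolve_instrument(two_peak, irf)
  expect_equal(spectrum_integral(blurred), spectrum_integral(two_peak),
               tolerance = 1e-9)
  # blur + restore: peak positions recovered within one bin
  restored <- deconvolve_instrument(blurred, irf, max_iter = 200, tol = 1e-9)
  peaks <- function(v) {
    k1 <- which.max(v * (g$centers < 560))
    k2 <- which.max(v * (g$centers >= 560))
    c(k1, k2)
  }
  expect_true(all(abs(peaks(restored$values) - peaks(two_peak$values)) <= 1))
  expect_true(all(restored$values >= 0))
  # convolve(deconvolve(x)) ~ x
  expect_equal(convolve_instrument(restored, irf)$values, blurred$values,
               tolerance = 1e-3 * max(blurred$values))
  expect_error(instrument_function(c(1, 1)), "odd")
  expect_error(instrument_function(c(-1, 1, 1)), "non-negative")
})

test_that("detected-spectra twin: pass-through and fluorescence scaling", {
  g <- test_grid(2)
  geo <- sphere_geometry()
  src <- make_fixture_source(g)
  # transparent sample: transmission reproduces the source shape
  void <- optical_component("void", g, mu_a = 0)
  vac <- layered_sample(list(list(thickness_mm = 4, n = 1,
                                  components = c(void = 1))), list(void = void))
  sim <- simulate_detected_spectra(vac, src, geo, 5e4, seed = 41)
  tv <- sim$transmission$values
  expect_equal(g$centers[which.max(tv)], 510.5 + 0.5, tolerance = 2)
  src_band <- g$centers > 490 & g$centers < 530
  expect_gt(sum(tv[src_band]), 0.99 * sum(tv))

  # phi_f = 0 removes all signal outside the source band
  s0 <- make_fixture_sample(g, "ethanol-c3", phi_f = 0)
  sim0 <- simulate_detected_spectra(s0, src, geo, 5e4, seed = 42)
  out_band <- g$centers > 545
  expect_equal(sum(sim0$reflectance$values[out_band]), 0)
  expect_equal(sum(sim0$transmission$values[out_band]), 0)

  # integrated fluorescence grows strictly with phi_f (common random numbers)
  fluor_band <- function(sim) sum(sim$reflectance$values[out_band]) +
    sum(sim$transmission$values[out_band])
  vals <- vapply(c(0.3, 0.6, 0.9), function(p) {
    s <- make_fixture_sample(g, "ethanol-c3", phi_f = p)
    fluor_band(simulate_detected_spectra(s, src, geo, 5e4, seed = 43))
  }, 0)
  expect_true(all(diff(vals) > 0))
})
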