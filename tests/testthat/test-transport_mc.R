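test_that("free-path sampling: boundary, mean, vacuum limit", {
  expect_equal(sample_free_path(1, 0), 0)
  expect_error(sample_free_path(-1, 0.5), "non-negative")
  expect_identical(sample_free_path(0, c(0.1, 0.9)), c(Inf, Inf))
  xi <- ld_uniforms(2e5)
  s <- sample_free_path(1, xi)
  expect_equal(mean(s), 1, tolerance = 3 / sqrt(length(xi)))  # exp mean=sd=1
})

test_that("absorption-vs-scattering decision follows P_abs", {
  expect_equal(choose_interaction(1, 1, 0.3), "absorb")    # P_abs = 0.5
  expect_equal(choose_interaction(1, 1, 0.7), "scatter")
  expect_equal(unique(choose_interaction(0, 2, ld_uniforms(100))), "scatter")
  expect_error(choose_interaction(0, 0, 0.5), "zero")
  frac <- mean(choose_interaction(1, 3, ld_uniforms(1e5)) == "absorb")
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
})

test_that("Henyey-Greenstein sampling: limits, quantile, first moment", {
  # isotropic limit
  xi <- ld_uniforms(1e5)
  expect_equal(mean(sample_hg_cosine(0, xi)), 0, tolerance = 3 / sqrt(3 * 1e5))
  # analytic quantile at g = 0.5, xi = 0.5 (numerically inverted HG CDF)
  expect_equal(sample_hg_cosine(0.5, 0.5), 0.6875, tolerance = 1e-12)
  # empirical mean cosine equals g
  for (gg in c(0.5, 0.9)) {
    cs <- sample_hg_cosine(gg, xi)
    expect_lt(abs(mean(cs) - gg), 3 * sd(cs) / sqrt(length(xi)) + 1e-4)
  }
  expect_error(sample_hg_cosine(1, 0.5), "-1, 1")
})

test_that("Fresnel boundary: index match, normal incidence, TIR", {
  expect_equal(fresnel_reflectance(1.5, 1.5, 0.7), 0)
  expect_equal(fresnel_reflectance(1, 1.5, 1), ((1 - 1.5) / (1 + 1.5))^2)
  # beyond the critical angle from glass to air: always reflected
  cos_crit <- sqrt(1 - (1 / 1.5)^2)
  expect_equal(fresnel_reflectance(1.5, 1, cos_crit * 0.5), 1)
  expect_error(fresnel_reflectance(-1, 1, 0.5), "positive")

  b <- boundary_interaction(c(0, 0, 1), 1.5, 1.5, 0.5)
  expect_true(b$crossed)
  expect_equal(b$direction, c(0, 0, 1))
  # reflection flips the normal component
  b2 <- boundary_interaction(c(0.6, 0, 0.8), 1, 1.5, 0.001)
  expect_false(b2$crossed)
  expect_equal(b2$direction, c(0.6, 0, -0.8))
  # Snell refraction preserves the tangential invariant n sin(theta)
  b3 <- boundary_interaction(c(0.6, 0, 0.8), 1, 1.5, 0.99)
  expect_true(b3$crossed)
  expect_equal(1.5 * sqrt(sum(b3$direction[1:2]^2)), 1 * 0.6, tolerance = 1e-12)
})

test_that("absorption subroutine: survival, termination, weight update", {
  g <- test_grid(1)
  dye <- make_fluorophore(g, phi_f = 1)
  sol <- make_solvent(g, mu_a = 0.1)
  reg <- list(fluorophore = dye, solvent = sol)
  s <- layered_sample(list(list(thickness_mm = 4, n = 1.36,
                                components = c(fluorophore = 1, solvent = 1))),
                      reg)
  ph <- list(lambda = 500, weight = 1, direction = c(0, 0, 1), n_cycles = 0L)
  co <- mixture_coefficients(s, 1, 500)

  # xi0 selecting the fluorophore, phi_f = 1: always re-emits
  out <- absorb_or_fluoresce(ph, co, reg, xi0 = 0.99, xi1 = 0.999,
                             xi2 = 0.3, xi3 = 0.6, xi_lambda = 0.5)
  expect_true(out$alive)
  expect_equal(out$n_cycles, 1L)
  expect_equal(out$weight, ph$lambda / out$lambda)   # Eq-of-motion of weight
  expect_equal(sqrt(sum(out$direction^2)), 1, tolerance = 1e-12)

  # phi_f = 0: always terminates in the fluorophore
  dye0 <- make_fluorophore(g, phi_f = 0)
  reg0 <- list(fluorophore = dye0, solvent = sol)
  out0 <- absorb_or_fluoresce(ph, co, reg0, 0.99, 0.001, 0.3, 0.6, 0.5)
  expect_false(out0$alive)
  expect_equal(out0$absorbed_in, "fluorophore")

  # xi0 below the base fraction: absorbed in the solvent
  outb <- absorb_or_fluoresce(ph, co, reg, xi0 = 0, xi1 = 0, xi2 = 0,
                              xi3 = 0, xi_lambda = 0.5)
  expect_false(outb$alive)
  expect_equal(outb$absorbed_in, "base")

  # explicit Stokes ratio: 500 -> 600 nm gives w = 5/6
  expect_equal(500 / 600, 0.833333, tolerance = 1e-6)
  lam_fixed <- sample_emission(dye$emission, 0.5)
  outw <- absorb_or_fluoresce(ph, co, reg, 0.99, 0.5, 0.5, 0.5, 0.5)
  expect_equal(outw$weight, 500 / lam_fixed)
})

test_that("vacuum sample transmits every photon with unit weight", {
  g <- test_grid(5)
  comp <- optical_component("void", g, mu_a = 0)
  s <- layered_sample(list(list(thickness_mm = 4, n = 1, components = c(void = 1))),
                      list(void = comp))
  t <- run_forward(s, narrow_source(g), 2e4, seed = 5)
  expect_equal(t$escaped, 2e4)
  expect_equal(sum(t$transmission$values), 2e4)
  expect_equal(sum(t$reflectance$values), 0)
  expect_true(all(t$records[, "weight"] == 1))
  expect_true(all(t$records[, "n_cycles"] == 0))
})

test_that("ballistic transmission of an absorbing slab is Beer-Lambert", {
  g <- test_grid(5)
  s <- absorbing_slab(g, mu_a = 0.1, d = 4)
  n <- 2e5
  t <- run_forward(s, narrow_source(g), n, seed = 2)
  p <- exp(-0.4)
  expect_lt(abs(t$escaped / n - p), 3 * sqrt(p * (1 - p) / n))
  # all escapes are forward ballistic
  expect_equal(sum(t$reflectance$values), 0)
})

test_that("launch wavelengths follow the source distribution", {
  g <- test_grid(1)
  comp <- optical_component("void", g, mu_a = 0)
  s <- layered_sample(list(list(thickness_mm = 1, n = 1, components = c(void = 1))),
                      list(void = comp))
  # delta-like source: single nonzero bin
  v <- numeric(g$n_bins); v[101] <- 3
  t <- run_forward(s, spectrum(g, v), 5000, seed = 8)
  expect_equal(unname(t$launch_counts[101]), 5000)
  # flat source over two bins: balanced within 3 sigma binomial
  v2 <- numeric(g$n_bins); v2[200:201] <- 1
  t2 <- run_forward(s, spectrum(g, v2), 4e4, seed = 9)
  expect_lt(abs(unname(t2$launch_counts[200]) / 4e4 - 0.5),
            3 * sqrt(0.25 / 4e4))
  # KS of continuous launch wavelengths against the source CDF
  src <- gaussian_source(g, 510, 20)
  t3 <- run_forward(s, src, 2e5, seed = 10)
  lam <- sort(t3$records[, "lambda_launch"])
  cdf_edges <- c(0, cumsum(src$values)) / sum(src$values)
  emp <- (seq_along(lam) - 0.5) / length(lam)
  model <- approx(g$edges, cdf_edges, xout = lam)$y
  expect_lt(max(abs(emp - model)), 0.004)   # 1% KS level at 2e5 draws
})

test_that("isotropic re-emission has zero mean direction cosine", {
  g <- test_grid(5)
  s <- make_fixture_sample(g, "bare-dye")
  t <- run_forward(s, make_fixture_source(g), 1e5, seed = 3)
  fl <- t$records[t$records[, "n_cycles"] >= 1, , drop = FALSE]
  # escaping fluorescence spreads over both hemispheres; crude isotropy check:
  # both sides populated with comparable counts
  n_r <- sum(fl[, "side"] == 0); n_t <- sum(fl[, "side"] == 1)
  expect_gt(n_r, 0.3 * n_t)
  expect_gt(n_t, 0.3 * n_r)
})

test_that("integer conservation and weight telescoping hold exactly", {
  g <- test_grid(2)
  s <- make_fixture_sample(g, "ethanol-c2")
  t <- run_forward(s, make_fixture_source(g), 5e4, seed = 12)
  expect_identical(t$launched, t$escaped + t$terminally_absorbed)
  r <- t$records
  expect_lt(max(abs(r[, "weight"] - r[, "lambda_launch"] / r[, "lambda"])),
            1e-12)
  expect_true(all(r[, "weight"] > 0))
  # ledger consistency: every absorption event either terminates or re-emits
  led <- t$absorption_ledger
  expect_equal(led$n_abs_primary + led$n_abs_secondary,
               led$n_terminal + led$n_emit)
  expect_equal(sum(led$n_terminal), t$terminally_absorbed)
})

test_that("phi_f = 1 never terminates inside the fluorophore", {
  g <- test_grid(2)
  s <- make_fixture_sample(g, "bare-dye", phi_f = 1)
  t <- run_forward(s, make_fixture_source(g), 2e4, seed = 4)
  led <- t$absorption_ledger
  expect_equal(led$n_terminal[led$component == "fluorophore"], 0)
  expect_equal(t$escaped, t$launched)
})

test_that("zero spectral overlap confines fluorescence to one cycle", {
  g <- test_grid(1)
  s <- make_fixture_sample(g, "zero-overlap")
  t <- run_forward(s, gaussian_source(g, 450, 8), 5e4, seed = 6)
  fl <- t$records[t$records[, "n_cycles"] >= 1, , drop = FALSE]
  expect_gt(nrow(fl), 0)
  expect_true(all(fl[, "n_cycles"] == 1))
})

test_that("quantum-yield estimators: definitions and degenerate equalities", {
  g <- test_grid(1)
  s <- make_fixture_sample(g, "bare-dye")          # no base absorber
  t <- run_forward(s, make_fixture_source(g), 1e5, seed = 13)
  led <- t$absorption_ledger
  intr <- estimate_quantum_yield(t, "intrinsic_def")
  expect_equal(intr, sum(led$n_emit) /
                 sum(led$n_abs_primary + led$n_abs_secondary))
  # without base absorption, gross and uncorrected share the denominator
  expect_equal(estimate_quantum_yield(t, "gross"),
               estimate_quantum_yield(t, "uncorrected"))
  # intrinsic estimator converges to the configured value (binomial error)
  n_abs <- sum(led$n_abs_primary + led$n_abs_secondary)
  expect_lt(abs(intr - 0.9), 3 * sqrt(0.9 * 0.1 / n_abs))
})

test_that("uncorrected yield is depressed by overlap, not without it", {
  g <- test_grid(1)
  s0 <- make_fixture_sample(g, "zero-overlap")
  t0 <- run_forward(s0, gaussian_source(g, 450, 8), 1e5, seed = 14)
  led <- t0$absorption_ledger
  n_prim <- sum(led$n_abs_primary[led$is_fluorescent])
  unc0 <- estimate_quantum_yield(t0, "uncorrected")
  intr0 <- estimate_quantum_yield(t0, "intrinsic_def")
  expect_lt(abs(unc0 - intr0), 3 * sqrt(0.9 * 0.1 / n_prim))
  s1 <- make_fixture_sample(g, "red-edge")
  t1 <- run_forward(s1, make_fixture_source(g), 1e5, seed = 14)
  expect_lt(estimate_quantum_yield(t1, "uncorrected"),
            estimate_quantum_yield(t1, "intrinsic_def"))
})

test_that("forward runs are bit-identical for a fixed seed", {
  g <- test_grid(2)
  s <- make_fixture_sample(g, "ethanol-c3")
  a <- run_forward(s, make_fixture_source(g), 2e4, seed = 99)
  b <- run_forward(s, make_fixture_source(g), 2e4, seed = 99)
  expect_identical(a$records, b$records)
  expect_identical(a$reflectance$values, b$reflectance$values)
  c2 <- run_forward(s, make_fixture_source(g), 2e4, seed = 100)
  expect_false(identical(a$records, c2$records))
})
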