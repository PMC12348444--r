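# Shared fixtures built in code; kept small so the default run stays fast.

test_grid <- function(step = 1) spectral_grid(350, 800, step)

# single-component absorbing slab, index matched (Beer-Lambert reference)
absorbing_slab <- function(grid, mu_a = 0.1, d = 4) {
  comp <- optical_component("abs", grid, mu_a = mu_a)
  layered_sample(list(list(thickness_mm = d, n = 1, components = c(abs = 1))),
                 list(abs = comp), n_above = 1, n_below = 1)
}

narrow_source <- function(grid, center = 550, fwhm = 5) {
  gaussian_source(grid, center, fwhm)
}

single_gauss_gmm <- function(mu = 550, sigma = 10, support = c(350, 800)) {
  # one dominant component; the two satellites carry (numerically) no weight
  emission_gmm(means = c(mu, mu + 60, mu + 120), sigmas = c(sigma, 10, 10),
               weights = c(1 - 2e-9, 1e-9), support = support)
}

# deterministic uniforms for sampling tests (golden-ratio low discrepancy)
ld_uniforms <- function(n) ((1:n) * 0.6180339887498949) %% 1
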