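#' Overlap-integral re-absorption probability
#'
#' Classical estimate of the probability that an emitted photon is
#' re-absorbed before escaping: the normalized emission distribution is
#' integrated against a Beer-Lambert extinction term over an effective path,
#' `a = integral P_f(lambda) (1 - exp(-mu_a(lambda) * l)) dlambda`.
#' The effective path is geometry-dependent; the default used elsewhere in
#' the package is half the emitting layer thickness (mid-layer emission).
#'
#' @param emission an `fc_emission_gmm`
#' @param mu_a absorption coefficient spectrum: an `fc_spectrum` or a
#'   numeric vector on the same grid as the emission support sampling
#' @param path_mm effective path length (mm), >= 0
#' @param grid grid on which to evaluate (required if `mu_a` is a bare
#'   vector)
#' @return re-absorption probability in `[0, 1]`
#' @export
reabsorption_probability <- function(emission, mu_a, path_mm, grid = NULL) {
  if (path_mm < 0) stop("path length must be non-negative")
  if (inherits(mu_a, "fc_spectrum")) {
    grid <- mu_a$grid
    mu_a <- mu_a$values
  }
  if (is.null(grid)) stop("supply mu_a as an fc_spectrum or give a grid")
  if (any(mu_a < 0)) stop("mu_a must be non-negative")
  p <- emission_pdf(emission, grid$centers)
  a <- sum(p * (1 - exp(-mu_a * path_mm))) * grid$step
  # renormalize for the part of the emission support covered by the grid
  mass <- sum(p) * grid$step
  if (mass <= 0) stop("emission has no mass on the grid")
  min(a / mass, 1)
}

#' Classical re-absorption correction of an observed quantum yield
#'
#' Maps an observed (cascade-biased) quantum yield back to the intrinsic
#' one given a re-absorption probability `a`:
#' `phi_f = phi_obs / (1 - a + a * phi_obs)`. Identity at `a = 0`; tends to
#' 1 for any positive `phi_obs` as `a -> 1`. Monotone increasing in both
#' arguments and maps the unit square into `[phi_obs, 1]`.
#'
#' @param phi_obs observed quantum yield in `[0, 1]`
#' @param a re-absorption probability in `[0, 1]`
#' @return corrected quantum yield
#' @export
correct_quantum_yield <- function(phi_obs, a) {
  if (any(phi_obs < 0 | phi_obs > 1)) stop("phi_obs must lie in [0, 1]")
  if (any(a < 0 | a > 1)) stop("a must lie in [0, 1]")
  den <- 1 - a + a * phi_obs
  if (any(den <= 0)) stop("degenerate correction denominator")
  phi_obs / den
}

#' Cycle-resolved decomposition of the escaping fluorescence
#'
#' Groups the escaping wavelength-converted photons of one detection side by
#' the number of absorption-emission cycles they underwent. The per-cycle
#' spectra partition the side's total fluorescence spectrum exactly. Cycles
#' at and beyond `pool_from` are pooled (few cycles dominate in practice);
#' the underlying records remain available in the tallies.
#'
#' @param tallies an `fc_tallies` with exit records
#' @param side `"reflectance"` or `"transmission"`
#' @param pool_from pool cycle counts `>= pool_from` (default 5)
#' @return object of class `fc_cycles`: `spectra` (matrix bins x groups),
#'   `counts`, `mean_wavelength` per group, `labels`, `side`
#' @export
cycle_decompose <- function(tallies, side = c("reflectance", "transmission"),
                            pool_from = 5L) {
  side <- match.arg(side)
  side_code <- if (side == "reflectance") 0 else 1
  recs <- tallies$records
  if (nrow(recs) == 0) stop("tallies carry no exit records")
  sel <- recs[, "side"] == side_code & recs[, "n_cycles"] >= 1
  recs <- recs[sel, , drop = FALSE]
  grid <- tallies$grid
  groups <- pmin(recs[, "n_cycles"], pool_from)
  present <- sort(unique(groups))
  labels <- ifelse(present >= pool_from, paste0(pool_from, "+"),
                   as.character(present))
  spectra <- matrix(0, grid$n_bins, length(present),
                    dimnames = list(NULL, labels))
  counts <- integer(length(present))
  meanw <- numeric(length(present))
  k <- grid_bin(grid, recs[, "lambda"])
  for (j in seq_along(present)) {
    s <- groups == present[j]
    tt <- tapply(recs[s, "weight"], k[s], sum)
    spectra[as.integer(names(tt)), j] <- tt
    counts[j] <- sum(s)
    meanw[j] <- sum(recs[s, "lambda"] * recs[s, "weight"]) /
      sum(recs[s, "weight"])
  }
  structure(list(spectra = spectra, counts = counts,
                 mean_wavelength = meanw, labels = labels, side = side,
                 grid = grid),
            class = "fc_cycles")
}

#' @export
print.fc_cycles <- function(x, ...) {
  cat(sprintf("<fc_cycles> %s side, %d cycle group(s)\n", x$side,
              length(x$labels)))
  for (j in seq_along(x$labels))
    cat(sprintf("  cycle %-3s n = %8d  mean lambda = %.2f nm\n",
                x$labels[j], x$counts[j], x$mean_wavelength[j]))
  invisible(x)
}

#' Compare quantum-yield estimators on one simulated run
#'
#' Assembles the three photon-count estimators (intrinsic definition,
#' uncorrected, gross; see [estimate_quantum_yield()]) and, when a sample is
#' supplied, the classical overlap-integral correction applied to the
#' uncorrected value. The physically expected ordering
#' `gross <= uncorrected <= intrinsic_def` is checked and flagged.
#'
#' @param tallies an `fc_tallies` from a fluorescent run
#' @param sample optional `fc_sample` used to compute the re-absorption
#'   probability (emission model of its first fluorescent component,
#'   absorption of the layer containing it)
#' @param path_mm effective path for the overlap integral. Default: the
#'   fluorescent layer thickness, i.e. the mid-layer geometric path `d/2`
#'   times the diffusivity factor 2 that accounts for the oblique escape
#'   paths of isotropic emission (the plain `d/2` path systematically
#'   underestimates re-absorption)
#' @return list with `intrinsic_def`, `uncorrected`, `gross`,
#'   `reabsorption_a`, `eq_corrected` (classical correction of the
#'   uncorrected yield; NA without a sample), `ordering_ok`
#' @export
compare_yields <- function(tallies, sample = NULL, path_mm = NULL) {
  intr <- estimate_quantum_yield(tallies, "intrinsic_def")
  unc <- estimate_quantum_yield(tallies, "uncorrected")
  gro <- estimate_quantum_yield(tallies, "gross")
  a <- NA_real_; corr <- NA_real_
  if (!is.null(sample)) {
    li <- NULL; comp <- NULL
    for (l in seq_along(sample$layers)) {
      for (nm in names(sample$layers[[l]]$components)) {
        if (sample$components[[nm]]$is_fluorescent) { li <- l; comp <- nm; break }
      }
      if (!is.null(li)) break
    }
    if (is.null(li)) stop("sample has no fluorescent component")
    if (is.null(path_mm)) path_mm <- sample$layers[[li]]$thickness_mm
    mu_tot <- numeric(sample$grid$n_bins)
    for (nm in names(sample$layers[[li]]$components))
      mu_tot <- mu_tot + sample$layers[[li]]$components[[nm]] *
        sample$components[[nm]]$mu_a
    a <- reabsorption_probability(sample$components[[comp]]$emission,
                                  spectrum(sample$grid, mu_tot), path_mm)
    corr <- correct_quantum_yield(unc, a)
  }
  list(intrinsic_def = intr, uncorrected = unc, gross = gro,
       reabsorption_a = a, eq_corrected = corr,
       ordering_ok = (gro <= unc + 1e-12) && (unc <= intr + 1e-12))
}
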