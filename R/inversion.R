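#' Replace the fluorescence parameters of a sample
#'
#' Returns a copy of the sample whose (first) fluorescent component carries
#' the given quantum yield and emission model; all other optical properties
#' are untouched. This is the parameter injection used by the fit: the
#' non-fluorescence properties are fixed inputs during optimization.
#'
#' @param sample an `fc_sample`
#' @param phi_f quantum yield in `[0, 1]`
#' @param gmm an `fc_emission_gmm`
#' @return the modified `fc_sample`
#' @export
set_fluorescence <- function(sample, phi_f, gmm) {
  for (nm in names(sample$components)) {
    if (sample$components[[nm]]$is_fluorescent) {
      sample$components[[nm]]$phi_f <- phi_f
      sample$components[[nm]]$emission <- gmm
      return(sample)
    }
  }
  stop("sample has no fluorescent component")
}

#' Root-mean-square error between simulated and measured spectrum pairs
#'
#' The fit objective: RMSE over the concatenated reflectance and
#' transmission vectors, unweighted.
#'
#' @param simulated,measured lists with `reflectance` and `transmission`
#'   `fc_spectrum` entries on a common grid
#' @return scalar RMSE
#' @export
objective_rmse <- function(simulated, measured) {
  if (!grids_identical(simulated$reflectance$grid, measured$reflectance$grid))
    stop("simulated and measured spectra are on different grids")
  r <- c(simulated$reflectance$values - measured$reflectance$values,
         simulated$transmission$values - measured$transmission$values)
  sqrt(mean(r^2))
}

# Transformed parameter vector <-> (phi_f, gmm); support is fixed.
# Means are parameterized as (first mean, log spacings): the dominant data
# mismatch of a wrongly placed emission comb is a collective shift of all
# three means, which this makes a single coordinate (and mean ordering is
# enforced by construction, removing label switching).
theta_pack <- function(phi_f, gmm) {
  w <- pmax(gmm$weights, 1e-8)
  m <- gmm$means
  d <- pmax(diff(m), 1e-3)
  c(stats::qlogis(min(max(phi_f, 1e-6), 1 - 1e-6)),
    m[1], log(d[1]), log(d[2]),
    log(gmm$sigmas), log(w[1] / w[3]), log(w[2] / w[3]))
}

# log-scale coordinates are clamped so damped trial steps cannot propose
# zero widths or astronomical spacings
clamp_exp <- function(x) exp(pmin(pmax(x, -8), 8))

theta_means <- function(theta) {
  m1 <- theta[2]
  c(m1, m1 + clamp_exp(theta[3]),
    m1 + clamp_exp(theta[3]) + clamp_exp(theta[4]))
}

theta_unpack <- function(theta, support) {
  e <- exp(pmin(pmax(c(theta[8], theta[9], 0), -30), 30))
  w <- e / sum(e)
  list(phi_f = stats::plogis(theta[1]),
       gmm = emission_gmm(theta_means(theta), clamp_exp(theta[5:7]), w,
                          support))
}

theta_names <- c("phi_f", "mu1", "mu2", "mu3", "sigma1", "sigma2", "sigma3",
                 "w1", "w2")

# natural-scale parameter vector and its Jacobian wrt theta (delta method)
theta_natural <- function(theta) {
  p <- stats::plogis(theta[1])
  e <- exp(c(theta[8], theta[9], 0)); w <- e / sum(e)
  c(p, theta_means(theta), clamp_exp(theta[5:7]), w[1], w[2])
}

theta_natural_jacobian <- function(theta) {
  G <- matrix(0, 9, 9)
  p <- stats::plogis(theta[1])
  G[1, 1] <- p * (1 - p)
  d1 <- exp(theta[3]); d2 <- exp(theta[4])
  G[2, 2] <- 1
  G[3, 2] <- 1; G[3, 3] <- d1
  G[4, 2] <- 1; G[4, 3] <- d1; G[4, 4] <- d2
  G[5:7, 5:7] <- diag(exp(theta[5:7]))
  e <- exp(c(theta[8], theta[9], 0)); w <- e / sum(e)
  G[8, 8] <- w[1] * (1 - w[1]); G[8, 9] <- -w[1] * w[2]
  G[9, 8] <- -w[2] * w[1];      G[9, 9] <- w[2] * (1 - w[2])
  G
}

#' Fit quantum yield and emission parameters to measured spectra
#'
#' Levenberg-Marquardt estimation of the 9 free parameters (quantum yield
#' plus three means, three standard deviations, and two weights of the
#' emission mixture) by minimizing the RMSE between the forward sphere twin
#' and the measured reflectance/transmission pair. Every objective
#' evaluation reuses the same RNG seed (common random numbers), so the
#' stochastic forward model becomes a deterministic function of the
#' parameters and finite-difference Jacobians are meaningful. Parameters
#' are optimized on transformed scales (logit for the yield, log for the
#' widths, additive log-ratio for the weights) to enforce their bounds
#' without constraints.
#'
#' Statistical errors come from the Gauss-Newton covariance
#' `sigma^2 (J'J)^-1` at the optimum, scaled by the residual variance and
#' mapped to the natural scale by the delta method; 95% confidence
#' intervals are `estimate +/- 1.96 se`.
#'
#' @param measured list with `reflectance` and `transmission`
#'   `fc_spectrum`s
#' @param sample an `fc_sample` with fixed non-fluorescence properties
#' @param source excitation `fc_spectrum`
#' @param geometry an `fc_sphere` or per-side list
#' @param init list with `phi_f` and `gmm` starting values; the emission
#'   support is frozen at `init$gmm$support`
#' @param n_photons photons per objective evaluation
#' @param seed common-random-numbers seed
#' @param irf optional `fc_irf` applied in the forward model
#' @param control list: `max_iter` (default 30), `fd_step` (per-parameter
#'   absolute finite-difference steps on the transformed scale; the
#'   defaults — 0.1 on the yield logit, 2 nm on the mean anchor, 0.1 on the
#'   log mean spacings, 0.05 on log widths,
#'   0.1 on weight log-ratios — are sized well above the residual Monte
#'   Carlo roughness that survives common random numbers, which a too-small
#'   step would amplify into a noise-dominated Jacobian), `lambda0`
#'   (initial damping, default 1e-3), `tol` (relative cost decrease,
#'   default 1e-7), `n_photons_aux` (auxiliary-run photons, default
#'   `n_photons`), `polish_evals` (budget for a derivative-free
#'   Nelder-Mead polish after LM terminates, default 0 = off; useful when
#'   the optimum sits in a valley too shallow for finite differences),
#'   `fd_cov_scale` (factor enlarging the finite-difference steps of the
#'   final covariance Jacobian, default 3: wider secants suppress the
#'   Monte Carlo roughness that would otherwise masquerade as curvature
#'   and shrink the reported errors), `weighting` (`"none"`, the default
#'   unweighted RMSE, or `"inverse_variance"`: residuals scaled by
#'   `1/sqrt(max(measured, floor))`, a Poisson-like noise model that stops
#'   the bright excitation peak from drowning the fluorescence-band
#'   information)
#' @return object of class `fc_fit`: `phi_f`, `gmm`, `estimates` (natural
#'   scale, named), `stat_error`, `ci95` (2-column matrix), `covariance`
#'   (9x9, natural scale), `rmse`, `n_iterations`, `n_evaluations`,
#'   `converged`
#' @export
fit_quantum_yield <- function(measured, sample, source, geometry, init,
                              n_photons, seed, irf = NULL, control = list()) {
  ctl <- utils::modifyList(list(max_iter = 30,
                                fd_step = c(0.1, 2, 0.1, 0.1, 0.05, 0.05,
                                            0.05, 0.1, 0.1),
                                lambda0 = 1e-3, tol = 1e-7,
                                n_photons_aux = n_photons,
                                polish_evals = 0, fd_cov_scale = 3,
                                weighting = "none"), control)
  support <- init$gmm$support
  y <- c(measured$reflectance$values, measured$transmission$values)
  wts <- if (identical(ctl$weighting, "inverse_variance")) {
    1 / sqrt(pmax(y, max(y) * 1e-3))
  } else rep(1, length(y))
  n_eval <- 0L
  resid_fn <- function(theta) {
    out <- tryCatch({
      par <- theta_unpack(theta, support)
      s <- set_fluorescence(sample, par$phi_f, par$gmm)
      sim <- simulate_detected_spectra(s, source, geometry, n_photons, seed,
                                       irf = irf,
                                       n_photons_aux = ctl$n_photons_aux)
      wts * (c(sim$reflectance$values, sim$transmission$values) - y)
    }, error = function(e) rep(1e6, length(y)))   # infeasible trial point
    n_eval <<- n_eval + 1L
    out
  }

  theta <- theta_pack(init$phi_f, init$gmm)
  r <- resid_fn(theta)
  cost <- sum(r^2)
  lam <- ctl$lambda0
  converged <- FALSE
  small_steps <- 0L
  iter <- 0L
  np <- length(theta)
  J <- matrix(0, length(r), np)
  while (iter < ctl$max_iter) {
    iter <- iter + 1L
    for (j in seq_len(np)) {
      h <- ctl$fd_step[j]
      tj <- theta; tj[j] <- tj[j] + h
      J[, j] <- (resid_fn(tj) - r) / h
    }
    A <- crossprod(J)
    gvec <- crossprod(J, r)
    accepted <- FALSE
    for (try in 1:10) {
      M <- A + lam * diag(diag(A) + 1e-12, np)
      delta <- tryCatch(solve(M, -gvec), error = function(e) NULL)
      if (is.null(delta)) { lam <- lam * 10; next }
      theta_new <- theta + as.numeric(delta)
      r_new <- resid_fn(theta_new)
      cost_new <- sum(r_new^2)
      if (cost_new < cost) {
        rel <- (cost - cost_new) / max(cost, 1e-300)
        theta <- theta_new; r <- r_new; cost <- cost_new
        lam <- max(lam / 3, 1e-12)
        accepted <- TRUE
        # declare convergence only after two consecutive iterations with
        # negligible improvement: a single small step can be a damped
        # move inside a shallow valley, not the optimum
        small_steps <- if (rel < ctl$tol || sqrt(sum(delta^2)) < 1e-9)
          small_steps + 1L else 0L
        if (small_steps >= 2L) converged <- TRUE
        break
      }
      lam <- lam * 5
    }
    if (!accepted) { converged <- TRUE; break }  # no improving step found
    if (converged) break
  }

  if (ctl$polish_evals > 0) {
    pol <- stats::optim(theta, function(th) sum(resid_fn(th)^2),
                        method = "Nelder-Mead",
                        control = list(maxit = ctl$polish_evals,
                                       parscale = ctl$fd_step,
                                       reltol = 1e-10))
    if (pol$value < cost) {
      theta <- pol$par
      r <- resid_fn(theta)
      cost <- sum(r^2)
    }
  }

  # covariance Jacobian on wider secants (less Monte Carlo roughness)
  for (j in seq_len(np)) {
    h <- ctl$fd_cov_scale * ctl$fd_step[j]
    tj <- theta; tj[j] <- tj[j] + h
    J[, j] <- (resid_fn(tj) - r) / h
  }
  # residual variance over informative bins only: bins with neither signal
  # nor parameter sensitivity have (near) zero residual AND zero variance,
  # and counting them in the degrees of freedom would deflate sigma^2 and
  # hence every reported uncertainty
  informative <- y > 0 | rowSums(abs(J)) > 0
  m <- max(sum(informative), np + 1)
  sigma2 <- cost / (m - np)
  A <- crossprod(J)
  cov_theta <- tryCatch(sigma2 * solve(A), error = function(e) {
    sigma2 * MASS_ginv(A)
  })
  G <- theta_natural_jacobian(theta)
  cov_nat <- G %*% cov_theta %*% t(G)
  cov_nat <- (cov_nat + t(cov_nat)) / 2
  est <- theta_natural(theta)
  names(est) <- theta_names
  se <- sqrt(pmax(diag(cov_nat), 0))
  names(se) <- theta_names
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  rownames(ci) <- theta_names
  par <- theta_unpack(theta, support)
  structure(list(phi_f = par$phi_f, gmm = par$gmm, estimates = est,
                 stat_error = se, ci95 = ci, covariance = cov_nat,
                 rmse = sqrt(cost / m), n_iterations = iter,
                 n_evaluations = n_eval, converged = converged,
                 theta = theta),
            class = "fc_fit")
}

# minimal pseudo-inverse fallback (avoids a MASS dependency)
MASS_ginv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @export
print.fc_fit <- function(x, ...) {
  cat(sprintf("<fc_fit> rmse = %.4g after %d iteration(s) (%d evaluations)%s\n",
              x$rmse, x$n_iterations, x$n_evaluations,
              if (x$converged) "" else "  [not converged]"))
  cat(sprintf("  phi_f = %.4f +/- %.4f  (95%% CI [%.4f, %.4f])\n",
              x$estimates["phi_f"], x$stat_error["phi_f"],
              x$ci95["phi_f", 1], x$ci95["phi_f", 2]))
  for (i in 1:3)
    cat(sprintf("  component %d: mu = %7.2f nm, sigma = %6.2f nm, w = %.3f\n",
                i, x$gmm$means[i], x$gmm$sigmas[i], x$gmm$weights[i]))
  invisible(x)
}
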