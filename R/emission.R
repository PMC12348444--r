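#' Intrinsic emission distribution as a three-component Gaussian mixture
#'
#' The intrinsic probability distribution of emitted wavelengths for a single
#' fluorescence event is modeled as a normalized mixture of three Gaussians,
#' truncated to a finite support and renormalized. Eight quantities are free:
#' three means, three standard deviations, and two weights (the third weight
#' is `1 - w1 - w2`). The distribution is excitation-independent: emission
#' occurs from the relaxed excited state regardless of the absorbed
#' wavelength (Kasha rule), so anti-Stokes sampling is permitted.
#'
#' @param means numeric length 3, component means (nm)
#' @param sigmas numeric length 3, component standard deviations (nm), > 0
#' @param weights numeric length 2 or 3; if length 2, the third weight is
#'   `1 - w1 - w2`; all weights must be >= 0 and sum to 1
#' @param support numeric length 2, truncation interval `[lmin, lmax]` (nm)
#' @return an object of class `fc_emission_gmm`; components are sorted by
#'   mean so fitted models are comparable
#' @export
emission_gmm <- function(means, sigmas, weights, support) {
  stopifnot(length(means) == 3, length(sigmas) == 3)
  if (length(weights) == 2L) weights <- c(weights, 1 - sum(weights))
  stopifnot(length(weights) == 3)
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  weights <- pmax(weights, 0); weights <- weights / sum(weights)
  if (length(support) != 2L || support[2] <= support[1])
    stop("support must be an increasing interval")
  ord <- order(means)
  means <- means[ord]; sigmas <- sigmas[ord]; weights <- weights[ord]
  # mass of the untruncated mixture inside the support (renormalization)
  z <- sum(weights * (stats::pnorm(support[2], means, sigmas) -
                        stats::pnorm(support[1], means, sigmas)))
  if (z <= 0) stop("mixture has no mass on the support")
  structure(list(means = means, sigmas = sigmas, weights = weights,
                 support = support, norm = z),
            class = "fc_emission_gmm")
}

#' @export
print.fc_emission_gmm <- function(x, ...) {
  cat("<fc_emission_gmm> support", sprintf("[%g, %g] nm\n", x$support[1], x$support[2]))
  for (i in 1:3)
    cat(sprintf("  mu = %8.3f nm  sigma = %7.3f nm  w = %.4f\n",
                x$means[i], x$sigmas[i], x$weights[i]))
  invisible(x)
}

#' Emission probability density
#'
#' Density per nm of the truncated-renormalized mixture; zero outside the
#' support (not an error). Integrates to 1 over the support.
#'
#' @param model an `fc_emission_gmm`
#' @param lambda wavelengths (nm), vectorized
#' @return densities (per nm)
#' @export
emission_pdf <- function(model, lambda) {
  d <- (model$weights[1] * stats::dnorm(lambda, model$means[1], model$sigmas[1]) +
        model$weights[2] * stats::dnorm(lambda, model$means[2], model$sigmas[2]) +
        model$weights[3] * stats::dnorm(lambda, model$means[3], model$sigmas[3])) /
    model$norm
  d[lambda < model$support[1] | lambda > model$support[2]] <- 0
  d
}

#' Emission cumulative distribution function
#' @inheritParams emission_pdf
#' @return CDF values in `[0, 1]`
#' @export
emission_cdf <- function(model, lambda) {
  lam <- pmin(pmax(lambda, model$support[1]), model$support[2])
  p <- (model$weights[1] * (stats::pnorm(lam, model$means[1], model$sigmas[1]) -
                              stats::pnorm(model$support[1], model$means[1], model$sigmas[1])) +
        model$weights[2] * (stats::pnorm(lam, model$means[2], model$sigmas[2]) -
                              stats::pnorm(model$support[1], model$means[2], model$sigmas[2])) +
        model$weights[3] * (stats::pnorm(lam, model$means[3], model$sigmas[3]) -
                              stats::pnorm(model$support[1], model$means[3], model$sigmas[3]))) /
    model$norm
  pmin(pmax(p, 0), 1)
}

#' Inverse-CDF sampling of emission wavelengths
#'
#' Deterministic map from uniforms to wavelengths: a coarse inverse by
#' monotone interpolation of the CDF on a fine grid, polished by two Newton
#' steps. Used both directly and (in tabulated form) by the transport kernel.
#'
#' @param model an `fc_emission_gmm`
#' @param xi uniform variates in `[0, 1)`, vectorized
#' @return wavelengths (nm) inside the support
#' @export
sample_emission <- function(model, xi) {
  if (any(xi < 0 | xi >= 1)) stop("xi must lie in [0, 1)")
  lam_grid <- seq(model$support[1], model$support[2], length.out = 4097L)
  cdf_grid <- emission_cdf(model, lam_grid)
  lam <- stats::approx(cdf_grid, lam_grid, xout = xi, ties = "ordered",
                       rule = 2)$y
  for (it in 1:2) {
    d <- emission_pdf(model, lam)
    ok <- d > 1e-300
    lam[ok] <- lam[ok] - (emission_cdf(model, lam[ok]) - xi[ok]) / d[ok]
    lam <- pmin(pmax(lam, model$support[1]), model$support[2])
  }
  lam[xi == 0] <- model$support[1]      # exact CDF boundary
  lam
}

#' Fit an emission mixture to a measured spectrum
#'
#' Initializes the intrinsic emission model from a measured fluorescence
#' spectrum: the spectrum is area-normalized and a three-component Gaussian
#' mixture is fitted by nonlinear least squares. The optimization runs from
#' three moment-based starting points (multi-start, to escape local minima)
#' and keeps the best; parameters are returned sorted by mean.
#'
#' @param measured an `fc_spectrum`, non-negative with a single dominant band
#' @param support truncation interval; default the grid range
#' @return an `fc_emission_gmm` with attributes `rss` (residual sum of
#'   squares of the density fit) and `converged`
#' @export
init_from_spectrum <- function(measured, support = NULL) {
  stopifnot(inherits(measured, "fc_spectrum"))
  v <- measured$values
  if (any(v < 0)) stop("measured spectrum must be non-negative")
  tot <- sum(v) * measured$grid$step
  if (tot <= 0) stop("measured spectrum is all zero")
  lam <- measured$grid$centers
  target <- v / tot                     # density per nm
  if (is.null(support)) support <- range(measured$grid$edges)

  # distribution summaries guiding the starting points
  cw <- cumsum(target) / sum(target)
  qtl <- function(p) lam[which.max(cw >= p)]
  m0 <- sum(lam * target) / sum(target)
  s0 <- sqrt(sum((lam - m0)^2 * target) / sum(target))
  peak <- lam[which.max(target)]

  # parameterization: first mean + log spacings (ordering by construction),
  # log sigmas, additive log-ratio weights
  unpack <- function(p) {
    m1 <- p[1]; m2 <- m1 + exp(p[2]); m3 <- m2 + exp(p[3])
    e <- exp(c(p[7], p[8], 0)); w <- e / sum(e)
    list(means = c(m1, m2, m3), sigmas = exp(p[4:6]), weights = w)
  }
  mk_start <- function(m, sg, w = c(1, 1, 1) / 3) {
    m <- sort(m)
    c(m[1], log(max(m[2] - m[1], 1)), log(max(m[3] - m[2], 1)), log(sg),
      log(w[1] / w[3]), log(w[2] / w[3]))
  }
  starts <- list(
    mk_start(c(qtl(0.15), qtl(0.5), qtl(0.85)), rep(s0 / 2, 3)),
    mk_start(c(peak, peak + s0, peak + 2.5 * s0), c(s0 / 2, s0 / 1.5, s0),
             c(0.6, 0.25, 0.15)),
    mk_start(c(m0 - s0, m0, m0 + s0), rep(s0 / 1.5, 3)))

  sse <- function(p) {
    q <- unpack(p)
    mod <- tryCatch(emission_gmm(q$means, q$sigmas, q$weights, support),
                    error = function(e) NULL)
    if (is.null(mod)) return(1e6)
    sum((emission_pdf(mod, lam) - target)^2)
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(stats::optim(p0, sse, method = "BFGS",
                                 control = list(maxit = 1000, reltol = 1e-14)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    # derivative-free polish escapes flat BFGS terminations
    fit <- stats::optim(fit$par, sse, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("emission fit failed to converge from every start")
  q <- unpack(best$par)
  out <- emission_gmm(q$means, q$sigmas, q$weights, support)
  attr(out, "rss") <- best$value
  attr(out, "converged") <- best$convergence == 0
  out
}

#' Serialize / deserialize an emission mixture
#'
#' Plain-list form (8 free parameters + support) for the JSON config format.
#' @param model an `fc_emission_gmm`
#' @return a named list
#' @export
gmm_to_list <- function(model) {
  list(means_nm = model$means, sigmas_nm = model$sigmas,
       weights = model$weights[1:2], support_nm = model$support)
}

#' @rdname gmm_to_list
#' @param x a list produced by `gmm_to_list` (or parsed from config)
#' @export
gmm_from_list <- function(x) {
  emission_gmm(as.numeric(x$means_nm), as.numeric(x$sigmas_nm),
               as.numeric(x$weights), as.numeric(x$support_nm))
}
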