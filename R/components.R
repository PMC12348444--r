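#' Optical properties of one material component
#'
#' One constituent of a sample layer: wavelength-resolved absorption and
#' scattering coefficients (per mm) and Henyey-Greenstein anisotropy, all on
#' a common grid, plus fluorescence attributes for fluorescent components
#' (quantum yield and the intrinsic emission distribution). Coefficients are
#' stored at reference concentration; layer mixtures scale them linearly by a
#' concentration weight (Beer-Lambert scaling).
#'
#' @param name component identifier (unique within a sample)
#' @param grid an `fc_grid`
#' @param mu_a absorption coefficient per mm, scalar or vector on bin centers
#' @param mu_s scattering coefficient per mm, scalar or vector
#' @param g anisotropy in (-1, 1), scalar or vector
#' @param is_fluorescent logical flag
#' @param phi_f fluorescence quantum yield in `[0, 1]` (fluorescent only)
#' @param emission an [emission_gmm()] (fluorescent only)
#' @return an object of class `fc_component`
#' @export
optical_component <- function(name, grid, mu_a, mu_s = 0, g = 0,
                              is_fluorescent = FALSE, phi_f = NULL,
                              emission = NULL) {
  stopifnot(inherits(grid, "fc_grid"))
  expand <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, grid$n_bins)
    if (length(x) != grid$n_bins)
      stop(what, " must be scalar or match the grid (", grid$n_bins, " bins)")
    as.numeric(x)
  }
  mu_a <- expand(mu_a, "mu_a"); mu_s <- expand(mu_s, "mu_s"); g <- expand(g, "g")
  if (any(mu_a < 0)) stop("mu_a must be non-negative")
  if (any(mu_s < 0)) stop("mu_s must be non-negative")
  if (any(abs(g) >= 1)) stop("anisotropy g must lie in (-1, 1)")
  if (is_fluorescent) {
    if (is.null(phi_f) || phi_f < 0 || phi_f > 1)
      stop("fluorescent components need phi_f in [0, 1]")
    if (!inherits(emission, "fc_emission_gmm"))
      stop("fluorescent components need an emission_gmm")
  } else {
    if (!is.null(phi_f) || !is.null(emission))
      stop("non-fluorescent components must not carry an emission model")
  }
  structure(list(name = name, grid = grid, mu_a = mu_a, mu_s = mu_s, g = g,
                 is_fluorescent = isTRUE(is_fluorescent),
                 phi_f = phi_f, emission = emission),
            class = "fc_component")
}

#' @export
print.fc_component <- function(x, ...) {
  cat(sprintf("<fc_component> '%s'%s: peak mu_a %.4g /mm, peak mu_s %.4g /mm\n",
              x$name, if (x$is_fluorescent)
                sprintf(" (fluorescent, phi_f = %.3g)", x$phi_f) else "",
              max(x$mu_a), max(x$mu_s)))
  invisible(x)
}

#' Read component optical properties from a delimited table
#'
#' The table must be comma-, tab- or whitespace-delimited with a header row
#' naming at least `wavelength_nm` and `mu_a_per_mm`; `mu_s_per_mm` and `g`
#' are optional (default 0). Values are interpolated linearly onto the grid
#' bin centers. The tabulated wavelength range must cover the full grid:
#' out-of-range bins raise an error rather than extrapolate.
#'
#' @param path file path
#' @param grid an `fc_grid`
#' @param name component name (default: file base name)
#' @inheritParams optical_component
#' @return an `fc_component`
#' @export
load_spectra_table <- function(path, grid, name = NULL,
                               is_fluorescent = FALSE, phi_f = NULL,
                               emission = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header)) "," else if (grepl("\t", header)) "\t" else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!"wavelength_nm" %in% names(tab)) stop("missing column: wavelength_nm")
  if (!"mu_a_per_mm" %in% names(tab)) stop("missing column: mu_a_per_mm")
  wl <- tab$wavelength_nm
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  interp <- function(col, default = 0) {
    if (!col %in% names(tab)) return(rep(default, grid$n_bins))
    y <- tab[[col]]
    if (col != "g" && any(y < 0)) stop("negative values in column ", col)
    out <- stats::approx(wl, y, xout = grid$centers, rule = 1)$y
    if (any(is.na(out)))
      stop(sprintf(
        "table in '%s' covers %g-%g nm but grid centers span %g-%g nm; refusing to extrapolate",
        path, min(wl), max(wl), min(grid$centers), max(grid$centers)))
    out
  }
  optical_component(name = if (is.null(name))
                      sub("\\.[^.]*$", "", basename(path)) else name,
                    grid = grid,
                    mu_a = interp("mu_a_per_mm"),
                    mu_s = interp("mu_s_per_mm"),
                    g = interp("g"),
                    is_fluorescent = is_fluorescent, phi_f = phi_f,
                    emission = emission)
}

#' Write component optical properties to a CSV table
#'
#' Inverse of [load_spectra_table()]: writes `wavelength_nm, mu_a_per_mm,
#' mu_s_per_mm, g` at the grid bin centers. Round trip reproduces values to
#' at least 6 significant digits.
#'
#' @param component an `fc_component`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_spectra_table <- function(component, path) {
  df <- data.frame(wavelength_nm = component$grid$centers,
                   mu_a_per_mm = component$mu_a,
                   mu_s_per_mm = component$mu_s,
                   g = component$g)
  utils::write.csv(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Layered slab sample
#'
#' An ordered stack of plane-parallel layers, illuminated from above (layer 1
#' faces the source; z = 0 at the illuminated surface, z increasing into the
#' sample). Each layer has a thickness, a refractive index (scalar or a
#' vector over the grid), and a concentration-weighted mixture of components.
#'
#' @param layers list of layers, each a list with fields `thickness_mm`
#'   (> 0), `n` (refractive index), and `components`: a named numeric vector
#'   of concentration weights (>= 0), names referring to `components`
#' @param components named list of `fc_component` objects (the registry)
#' @param n_above,n_below refractive index of the surrounding medium on the
#'   illuminated / far side (default air)
#' @return an object of class `fc_sample`
#' @export
layered_sample <- function(layers, components, n_above = 1, n_below = 1) {
  if (length(layers) < 1L) stop("a sample needs at least one layer")
  if (is.null(names(components)) || any(names(components) == ""))
    stop("components must be a named list")
  grid <- components[[1]]$grid
  for (cm in components) {
    stopifnot(inherits(cm, "fc_component"))
    if (!grids_identical(cm$grid, grid)) stop("components are on different grids")
  }
  for (ly in layers) {
    if (!is.numeric(ly$thickness_mm) || ly$thickness_mm <= 0)
      stop("layer thicknesses must be positive")
    if (any(ly$n <= 0)) stop("refractive indices must be positive")
    w <- ly$components
    if (is.null(names(w)) || any(!names(w) %in% names(components)))
      stop("layer references unknown component")
    if (any(w < 0)) stop("component weights must be non-negative")
  }
  if (n_above <= 0 || n_below <= 0) stop("ambient indices must be positive")
  structure(list(layers = layers, components = components, grid = grid,
                 n_above = n_above, n_below = n_below),
            class = "fc_sample")
}

#' @export
print.fc_sample <- function(x, ...) {
  cat(sprintf("<fc_sample> %d layer(s), total thickness %.3g mm, %d component(s)\n",
              length(x$layers), sum(vapply(x$layers, `[[`, 0, "thickness_mm")),
              length(x$components)))
  invisible(x)
}

#' Total geometric thickness of a sample (mm)
#' @param sample an `fc_sample`
#' @export
sample_thickness <- function(sample)
  sum(vapply(sample$layers, `[[`, 0, "thickness_mm"))

#' Concentration-weighted optical coefficients of a layer at one wavelength
#'
#' Resolves the mixture of a layer at wavelength `lambda`: the base (non-
#' fluorescent) absorption, the per-fluorophore absorption list, and the
#' per-component scattering list, each scaled linearly by its concentration
#' weight. The total absorption is `mu_a_base + sum(mu_a_fluo)`.
#'
#' @param sample an `fc_sample`
#' @param layer 1-based layer index
#' @param lambda wavelength (nm), must fall inside the grid
#' @return list with `mu_a_base`, named `mu_a_fluo`, named `mu_s`, named `g`,
#'   and `mu_a_tot`, `mu_s_tot`, `mu_t`
#' @export
mixture_coefficients <- function(sample, layer, lambda) {
  if (layer < 1L || layer > length(sample$layers)) stop("unknown layer index")
  k <- grid_bin(sample$grid, lambda)
  if (is.na(k)) stop("wavelength outside the grid")
  w <- sample$layers[[layer]]$components
  mu_a_base <- 0
  mu_a_fluo <- numeric(0); mu_s <- numeric(0); g <- numeric(0)
  for (nm in names(w)) {
    cm <- sample$components[[nm]]
    if (cm$is_fluorescent) {
      mu_a_fluo[nm] <- w[[nm]] * cm$mu_a[k]
    } else {
      mu_a_base <- mu_a_base + w[[nm]] * cm$mu_a[k]
    }
    if (cm$mu_s[k] > 0 && w[[nm]] > 0) {
      mu_s[nm] <- w[[nm]] * cm$mu_s[k]
      g[nm] <- cm$g[k]
    }
  }
  list(mu_a_base = mu_a_base, mu_a_fluo = mu_a_fluo, mu_s = mu_s, g = g,
       mu_a_tot = mu_a_base + sum(mu_a_fluo),
       mu_s_tot = sum(mu_s),
       mu_t = mu_a_base + sum(mu_a_fluo) + sum(mu_s))
}

# Resolve an fc_sample into the flat per-layer arrays consumed by the C++
# transport kernel. Component order is the registry order; fluorescent
# components additionally carry phi_f and a tabulated emission CDF at the
# grid bin edges (piecewise-linear inverse sampling inside the kernel).
resolve_sample <- function(sample) {
  grid <- sample$grid
  comp_names <- names(sample$components)
  ncomp <- length(comp_names)
  is_fluo <- vapply(sample$components, `[[`, TRUE, "is_fluorescent")
  phi_f <- vapply(sample$components,
                  function(cm) if (cm$is_fluorescent) cm$phi_f else 0, 0)
  em_cdf <- matrix(0, nrow = grid$n_bins + 1L, ncol = ncomp)
  for (j in seq_len(ncomp)) {
    cm <- sample$components[[j]]
    if (cm$is_fluorescent)
      em_cdf[, j] <- emission_cdf(cm$emission, grid$edges)
  }
  nlay <- length(sample$layers)
  mu_a <- vector("list", nlay); mu_s <- vector("list", nlay)
  gmat <- vector("list", nlay); n_of <- vector("list", nlay)
  for (l in seq_len(nlay)) {
    ly <- sample$layers[[l]]
    A <- matrix(0, grid$n_bins, ncomp); S <- A; G <- A
    for (nm in names(ly$components)) {
      j <- match(nm, comp_names)
      cm <- sample$components[[nm]]
      A[, j] <- ly$components[[nm]] * cm$mu_a
      S[, j] <- ly$components[[nm]] * cm$mu_s
      G[, j] <- cm$g
    }
    mu_a[[l]] <- A; mu_s[[l]] <- S; gmat[[l]] <- G
    n_of[[l]] <- if (length(ly$n) == 1L) rep(ly$n, grid$n_bins) else as.numeric(ly$n)
    if (length(n_of[[l]]) != grid$n_bins)
      stop("layer refractive index must be scalar or a full grid vector")
  }
  list(edges = grid$edges, step = grid$step, n_bins = grid$n_bins,
       z_bounds = c(0, cumsum(vapply(sample$layers, `[[`, 0, "thickness_mm"))),
       comp_names = comp_names, is_fluo = as.integer(is_fluo),
       phi_f = phi_f, em_cdf = em_cdf,
       mu_a = mu_a, mu_s = mu_s, g = gmat, n_layer = n_of,
       n_above = sample$n_above, n_below = sample$n_below)
}
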