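#' Read a sample/instrument configuration file
#'
#' The configuration is a JSON document describing the wavelength grid, the
#' component registry (property tables plus fluorescence attributes), the
#' layer stack, the ambient indices, and optionally the source line and the
#' sphere geometry. Property-table paths are resolved relative to the
#' config file. See `make_fixture_config()` for a generated example.
#'
#' @param path path to the JSON config
#' @return list with `grid`, `sample`, and (if present) `source`,
#'   `geometry`, `irf`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  dir <- dirname(normalizePath(path))
  g <- cfg$grid
  grid <- spectral_grid(g$min_nm, g$max_nm, g$step_nm)
  comps <- list()
  for (nm in names(cfg$components)) {
    cc <- cfg$components[[nm]]
    fluo <- isTRUE(cc$is_fluorescent)
    emission <- if (fluo) gmm_from_list(cc$emission) else NULL
    comps[[nm]] <- load_spectra_table(file.path(dir, cc$table), grid,
                                      name = nm, is_fluorescent = fluo,
                                      phi_f = if (fluo) cc$phi_f else NULL,
                                      emission = emission)
  }
  layers <- lapply(cfg$layers, function(ly) {
    list(thickness_mm = ly$thickness_mm, n = ly$n,
         components = unlist(ly$components))
  })
  amb <- if (!is.null(cfg$ambient)) cfg$ambient else list(n_above = 1, n_below = 1)
  sample <- layered_sample(layers, comps,
                           n_above = amb$n_above, n_below = amb$n_below)
  out <- list(grid = grid, sample = sample)
  if (!is.null(cfg$source)) {
    out$source <- if (!is.null(cfg$source$table)) {
      tab <- utils::read.csv(file.path(dir, cfg$source$table))
      v <- stats::approx(tab$wavelength_nm, tab$power, xout = grid$centers,
                         rule = 2)$y
      spectrum(grid, pmax(v, 0))
    } else {
      gaussian_source(grid, cfg$source$center_nm, cfg$source$fwhm_nm,
                      if (is.null(cfg$source$power)) 1 else cfg$source$power)
    }
  }
  if (!is.null(cfg$sphere)) {
    sp <- cfg$sphere
    ports <- lapply(sp$ports, function(p)
      list(radius_mm = p$radius_mm, axis = as.numeric(p$axis),
           rho = if (is.character(p$rho)) p$rho else as.numeric(p$rho)))
    out$geometry <- sphere_geometry(
      diameter_mm = sp$diameter_mm, wall_rho = sp$wall_rho, ports = ports,
      fov = list(axis = as.numeric(sp$fov$axis),
                 half_angle_deg = sp$fov$half_angle_deg),
      mirror = sp$mirror)
  }
  if (!is.null(cfg$irf_fwhm_nm)) out$irf <- gaussian_irf(grid, cfg$irf_fwhm_nm)
  out
}

#' Validate a configuration file
#'
#' Builds every object in the config (which enforces all invariants) and
#' returns a one-line-per-item summary; any violated invariant raises an
#' error naming the offending field.
#'
#' @param path path to the JSON config
#' @return character vector of summary lines, invisibly printed
#' @export
validate_config <- function(path) {
  cfg <- read_config(path)
  lines <- c(
    sprintf("grid: %g-%g nm, %d bins of %g nm",
            cfg$grid$edges[1], cfg$grid$edges[length(cfg$grid$edges)],
            cfg$grid$n_bins, cfg$grid$step),
    sprintf("sample: %d layer(s), %.3g mm total, components: %s",
            length(cfg$sample$layers), sample_thickness(cfg$sample),
            paste(names(cfg$sample$components), collapse = ", ")),
    if (!is.null(cfg$source))
      sprintf("source: total power %.4g", spectrum_integral(cfg$source)),
    if (!is.null(cfg$geometry))
      sprintf("sphere: d = %g mm, wall rho %.3g, %d ports",
              2 * cfg$geometry$radius_mm, cfg$geometry$wall_rho[1],
              length(cfg$geometry$ports)))
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' Write a complete fixture configuration to a directory
#'
#' Materializes one of the synthetic presets as files a user could edit:
#' per-component property tables (CSV) plus a JSON config referencing them.
#'
#' @param dir output directory (created if needed)
#' @param preset fixture preset name (see [make_fixture_sample()])
#' @param grid an `fc_grid`
#' @param mus_prime reduced scattering level for the scattering presets
#' @return the config path, invisibly
#' @export
make_fixture_config <- function(dir, preset = "ethanol-c3",
                                grid = spectral_grid(), mus_prime = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sample <- make_fixture_sample(grid, preset, mus_prime = mus_prime)
  comps <- list()
  for (nm in names(sample$components)) {
    cm <- sample$components[[nm]]
    tab <- paste0(nm, ".csv")
    write_spectra_table(cm, file.path(dir, tab))
    comps[[nm]] <- c(list(table = tab),
                     if (cm$is_fluorescent)
                       list(is_fluorescent = TRUE, phi_f = cm$phi_f,
                            emission = gmm_to_list(cm$emission)))
  }
  cfg <- list(
    grid = list(min_nm = grid$edges[1],
                max_nm = grid$edges[length(grid$edges)],
                step_nm = grid$step),
    components = comps,
    layers = lapply(sample$layers, function(ly)
      list(thickness_mm = ly$thickness_mm, n = ly$n,
           components = as.list(ly$components))),
    ambient = list(n_above = sample$n_above, n_below = sample$n_below),
    source = list(center_nm = 510, fwhm_nm = 10, power = 1),
    sphere = list(
      diameter_mm = 150, wall_rho = 0.97,
      ports = list(
        sample = list(radius_mm = 12.5, axis = c(0, 0, -1), rho = "sample"),
        reflection = list(radius_mm = 12.5, axis = c(0, 0, 1), rho = "wall"),
        normalization = list(radius_mm = 12.5, axis = c(-1, 0, 0), rho = 0),
        detector = list(radius_mm = 6, axis = c(1, 0, 0), rho = 0)),
      fov = list(axis = c(0, 0.6, 0.8), half_angle_deg = 10),
      mirror = NULL),
    irf_fwhm_nm = 3.7)
  path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a fit result to a structured text report
#'
#' @param fit an `fc_fit`
#' @param path output path (JSON)
#' @return `path`, invisibly
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(estimates = as.list(fit$estimates),
              stat_error = as.list(fit$stat_error),
              ci95 = apply(fit$ci95, 1, as.list),
              rmse = fit$rmse,
              n_iterations = fit$n_iterations,
              converged = fit$converged,
              emission_support_nm = fit$gmm$support)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
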