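# Orchestration: one configuration object drives simulate -> hypsometry ->
# volumes -> climatology/indicators -> GAM -> regression screen, writing
# every stage product plus a machine-readable manifest.

#' Pipeline run configuration
#'
#' In simulation mode (the default) all inputs come from the seeded
#' synthetic lake; supplying \code{paths} (named list with any of
#' \code{raster}, \code{levels}, \code{profiles}, \code{survey}) switches
#' the corresponding stage to reading files instead.
#'
#' @param sim a \code{\link{lake_sim_config}}.
#' @param ranges named list of \code{\link{squeeze_range}}.
#' @param scenarios stressor scenarios to evaluate.
#' @param windows press-indicator window lengths, days.
#' @param depths depth planes (m); \code{0:10} evaluates eleven one-metre
#'   planes, \code{0:9} the ten-plane variant.
#' @param gam_k GAM basis dimensions (see \code{\link{fit_squeeze_gam}}).
#' @param alpha family-wise significance level for the screen.
#' @param survey_lag survey-to-indicator year offset.
#' @param survey_specs list of \code{\link{survey_effect_spec}} used in
#'   simulation mode.
#' @param paths optional named list of input file paths.
#' @param output_dir directory for stage outputs.
#' @param make_plots write summary PNG figures.
#' @param seed master seed (overrides \code{sim$seed}).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(sim = lake_sim_config(),
                       ranges = default_squeeze_ranges(),
                       scenarios = stressor_scenarios(),
                       windows = c(14, 30),
                       depths = 0:10,
                       gam_k = c(lag = 10, doy = 20, date = 10, level = 10),
                       alpha = 0.05,
                       survey_lag = 1,
                       survey_specs = default_survey_specs(),
                       paths = NULL,
                       output_dir = tempfile("habsqueeze_run_"),
                       make_plots = FALSE,
                       seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  if (length(ranges) == 0) stop("invalid config: ranges must be non-empty")
  if (!is.null(paths))
    for (p in unlist(paths))
      if (!file.exists(p)) stop("invalid config: input path not found: ", p)
  structure(list(sim = sim, ranges = ranges, scenarios = scenarios,
                 windows = windows, depths = depths, gam_k = gam_k,
                 alpha = alpha, survey_lag = survey_lag,
                 survey_specs = survey_specs, paths = paths,
                 output_dir = output_dir, make_plots = make_plots),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys override \code{\link{lake_sim_config}} fields; the keys
#' \code{windows}, \code{depths}, \code{alpha}, \code{survey_lag},
#' \code{output_dir}, \code{make_plots}, \code{seed} and a \code{paths}
#' block override the corresponding \code{\link{run_config}} arguments.
#'
#' @param path YAML file path.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_keys <- intersect(names(y), names(formals(lake_sim_config)))
  sim <- do.call(lake_sim_config, y[sim_keys])
  args <- y[intersect(names(y), setdiff(names(formals(run_config)), "sim"))]
  do.call(run_config, c(list(sim = sim), args))
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full habitat-squeeze pipeline
#'
#' Executes simulate (or load) -> hypsometric curve -> daily volumes ->
#' climatology, autocorrelation and annual indicators -> one GAM per
#' squeeze range -> survey regression screen, writing each stage table as
#' CSV plus a JSON run manifest (config hash, seed, row counts) under
#' \code{config$output_dir}.  Reruns with the same config and seed
#' reproduce byte-identical stage CSVs.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a list with every stage product and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- config$paths %||% list()
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))

  grid <- stage("bathymetry",
    if (!is.null(paths$raster)) read_elevation_raster(paths$raster)
    else generate_bathymetry(config$sim))
  levels <- stage("levels",
    if (!is.null(paths$levels)) read_levels_csv(paths$levels)
    else generate_water_levels(config$sim))
  profiles <- stage("profiles",
    if (!is.null(paths$profiles)) read_profiles_csv(paths$profiles)
    else generate_profiles(levels$date, levels, config$sim))

  curve <- stage("hypsometry", build_hypsometric_curve(grid))
  volumes <- stage("volumes",
    volume_series(curve, levels, profiles, ranges = config$ranges,
                  scenarios = config$scenarios, depths = config$depths))
  climatology <- stage("climatology", seasonal_climatology(volumes))
  indicators <- stage("indicators",
    annual_indicators(volumes, windows = config$windows))
  rho1 <- vapply(names(config$ranges), function(rn)
    lag1_autocorrelation(volumes, rn), numeric(1))

  gam_fits <- list(); gam_terms <- list(); gam_partials <- list()
  for (rn in names(config$ranges)) {
    fit <- stage(paste0("gam_", rn), {
      rows <- prepare_gam_table(volumes, levels, rn)
      fit_squeeze_gam(rows, k = config$gam_k)
    })
    gam_fits[[rn]] <- fit
    gam_terms[[rn]] <- cbind(range = rn, fit$terms,
                             r_sq = fit$r_sq, n = fit$n)
    gam_partials[[rn]] <- cbind(range = rn, fit$partial_effects)
  }
  gam_terms <- do.call(rbind, gam_terms)
  gam_partials <- do.call(rbind, gam_partials)

  survey <- stage("survey",
    if (!is.null(paths$survey)) read_survey_csv(paths$survey)
    else generate_survey(years = (min(config$sim$years) + 1):
                                 (max(config$sim$years) + 1),
                         indicators = indicators,
                         specs = config$survey_specs,
                         seed = config$sim$seed))
  screen <- stage("screen", {
    paired <- align_survey_to_indicators(survey, indicators,
                                         lag = config$survey_lag)
    run_screen(paired, alpha = config$alpha)
  })

  out <- config$output_dir
  files <- c(
    raster = write_elevation_raster(grid, file.path(out, "bathymetry.asc")),
    levels = write_stage_csv(levels, out, "water_levels"),
    profiles = write_stage_csv(profiles, out, "profiles"),
    hypsometry = write_stage_csv(as.data.frame(curve), out, "hypsometric_curve"),
    volumes = write_stage_csv(volumes, out, "daily_volumes"),
    climatology = write_stage_csv(climatology, out, "climatology"),
    indicators = write_stage_csv(indicators, out, "annual_indicators"),
    gam_terms = write_stage_csv(gam_terms, out, "gam_terms"),
    gam_partials = write_stage_csv(gam_partials, out, "gam_partial_effects"),
    survey = write_stage_csv(survey, out, "survey"),
    screen = write_stage_csv(as.data.frame(screen), out, "screen_results"))

  summary_txt <- file.path(out, "screen_summary.txt")
  s <- screen_summary(screen)
  writeLines(c(
    sprintf("Regression screen: %d models", s$n_models),
    sprintf("alpha = %g, Bonferroni-corrected alpha = %g",
            s$alpha, s$alpha_corrected),
    sprintf("p-values range %.4g .. %.4g", s$min_p, s$max_p),
    sprintf("significant at corrected alpha: %d", s$n_significant_corrected),
    sprintf("significant at nominal alpha: %d", s$n_significant_nominal)),
    summary_txt)

  if (isTRUE(config$make_plots))
    plot_pipeline_figures(climatology, gam_partials, out)

  manifest <- list(
    seed = config$sim$seed,
    config_hash = config_hash(deparse(unclass_recursive(config))),
    n_dates = length(unique(volumes$date)),
    n_ranges = length(config$ranges),
    n_scenarios = length(config$scenarios),
    n_volume_rows = nrow(volumes),
    n_skipped_dates = length(attr(volumes, "skipped_dates")),
    n_missing_planes = attr(volumes, "n_missing_planes"),
    n_indicator_rows = nrow(indicators),
    n_regressions = nrow(screen),
    lag1_autocorrelation = as.list(rho1),
    gam_r_sq = lapply(gam_fits, function(f) f$r_sq),
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(grid = grid, curve = curve, levels = levels,
                 profiles = profiles, volumes = volumes,
                 climatology = climatology, indicators = indicators,
                 lag1_autocorrelation = rho1, gam_fits = gam_fits,
                 survey = survey, screen = screen, manifest = manifest,
                 output_dir = out))
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}

# Stage-input readers ------------------------------------------------------

#' Read a daily water-level CSV (date, level_m)
#' @param path CSV path.
#' @return a \code{water_level_series}.
#' @export
read_levels_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("date", "level_m") %in% names(df)))
  df$date <- as.Date(df$date)
  structure(df, class = c("water_level_series", "data.frame"))
}

#' Read a profile CSV (date, depth_m, temp_c, do_mgl)
#' @param path CSV path.
#' @return a \code{profile_series}.
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("date", "depth_m", "temp_c", "do_mgl") %in% names(df)))
  df$date <- as.Date(df$date)
  structure(df, class = c("profile_series", "data.frame"))
}

#' Read an annual survey CSV (year, descriptor, value)
#' @param path CSV path.
#' @return a \code{survey_table}.
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("year", "descriptor", "value") %in% names(df)))
  structure(df, class = c("survey_table", "data.frame"))
}

# Figures ------------------------------------------------------------------

# Climatology panels per squeeze range (mean +/- sd envelope, with the
# no-stressor control) and the GAM partial-effect grid.
plot_pipeline_figures <- function(climatology, gam_partials, out) {
  ranges <- setdiff(unique(climatology$range), NA)
  grDevices::png(file.path(out, "climatology.png"), width = 900,
                 height = 300 * length(ranges), res = 96)
  graphics::par(mfrow = c(length(ranges), 1), mar = c(4, 4, 2, 1))
  for (rg in ranges) {
    both <- climatology[climatology$range == rg &
                        climatology$scenario == "both", ]
    none <- climatology[climatology$range == rg &
                        climatology$scenario == "none", ]
    graphics::plot(both$doy, both$mean_m3, type = "n",
                   ylim = range(0, none$mean_m3, both$mean_m3 + both$sd_m3),
                   xlab = "day of year", ylab = "volume (m^3)",
                   main = sprintf("mean seasonal suitable volume: %s", rg))
    graphics::polygon(c(both$doy, rev(both$doy)),
                      c(both$mean_m3 + both$sd_m3,
                        rev(pmax(both$mean_m3 - both$sd_m3, 0))),
                      col = "grey85", border = NA)
    if (nrow(none)) graphics::lines(none$doy, none$mean_m3, col = "darkgreen")
    graphics::lines(both$doy, both$mean_m3, lwd = 2)
  }
  grDevices::dev.off()

  if (!is.null(gam_partials) && nrow(gam_partials)) {
    terms <- unique(gam_partials$term)
    grDevices::png(file.path(out, "gam_partial_effects.png"),
                   width = 300 * length(terms),
                   height = 300 * length(ranges), res = 96)
    graphics::par(mfrow = c(length(ranges), length(terms)),
                  mar = c(4, 4, 2, 1))
    for (rg in ranges) for (tm in terms) {
      sub <- gam_partials[gam_partials$range == rg & gam_partials$term == tm, ]
      if (!nrow(sub)) { graphics::plot.new(); next }
      graphics::plot(sub$grid_value, sub$effect, type = "l", lwd = 2,
                     xlab = tm, ylab = "partial effect",
                     main = sprintf("%s: %s", rg, tm))
      graphics::lines(sub$grid_value, sub$effect + 2 * sub$se, col = "grey60")
      graphics::lines(sub$grid_value, sub$effect - 2 * sub$se, col = "grey60")
    }
    grDevices::dev.off()
  }
  invisible(NULL)
}
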