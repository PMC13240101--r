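# Seeded synthetic-lake generators: bathymetry, water levels, stratified
# temperature/DO profiles, and annual gillnet-style survey metrics.  These
# stand in for field inputs so every downstream stage of the squeeze
# analysis can be exercised end to end.

#' Synthetic lake configuration
#'
#' Bundles every parameter of the synthetic reservoir: basin geometry,
#' water-level dynamics, seasonal thermal stratification with hypolimnetic
#' oxygen depletion, simulation years, optional data gaps, and the master
#' RNG seed.
#'
#' The defaults describe a large south-central US reservoir: a bowl-shaped
#' basin spanning 165--195 m AMSL sampled on a ~486 m grid, a mean pool of
#' 188 m AMSL with seasonal and persistent (AR(1)) level variation, summer
#' surface temperatures approaching 30 degC, and a stratified season
#' (roughly late May to early October) during which dissolved oxygen below
#' the oxycline is drawn down towards \code{hypolimnion_do_floor}.
#'
#' @param grid_rows,grid_cols raster dimensions (>= 3).
#' @param cell_size raster cell edge length in metres.
#' @param basin_min_elev,basin_rim_elev deepest-point and rim elevations,
#'   m AMSL (\code{basin_min_elev < basin_rim_elev}).
#' @param basin_roughness_sd sd (m) of seeded Gaussian roughness added to
#'   the smooth bowl; 0 disables it.
#' @param mean_level long-run mean water-surface level, m AMSL.
#' @param level_seasonal_amp amplitude (m) of the seasonal level sinusoid.
#' @param level_ar1_phi AR(1) coefficient of the level residual, in [0, 1).
#' @param level_noise_sd innovation sd (m) of the level residual.
#' @param surf_temp_mean,surf_temp_amp annual mean and amplitude (degC) of
#'   the surface-temperature sinusoid.
#' @param surf_temp_peak_doy day of year of the surface-temperature peak.
#' @param strat_temp_drop maximum epilimnion-to-hypolimnion temperature
#'   difference (degC) at the height of stratification.
#' @param strat_depth_mid mid-depth (m) of the thermocline/oxycline logistic.
#' @param strat_width logistic width (m) of the thermocline/oxycline.
#' @param hypolimnion_do_floor asymptotic deep-water DO (mg/L) at peak
#'   stratification.
#' @param epilimnion_do mixed-layer DO (mg/L).
#' @param strat_onset_doy,strat_end_doy day-of-year window of stratification.
#' @param profile_noise_sd sd of optional observation noise added to
#'   temperature (degC) and DO (mg/L); 0 disables it.
#' @param years integer vector of calendar years to simulate.
#' @param gap_dates optional list of length-2 date vectors; days falling in
#'   any \code{[from, to]} interval are removed from generated levels (and
#'   hence profiles), emulating instrument outages.
#' @param seed master integer seed; all generator randomness derives from it.
#' @return object of class \code{lake_sim_config}.
#' @export
lake_sim_config <- function(grid_rows = 50, grid_cols = 50,
                            cell_size = 486.06,
                            basin_min_elev = 165, basin_rim_elev = 195,
                            basin_roughness_sd = 0,
                            mean_level = 188,
                            level_seasonal_amp = 2,
                            level_ar1_phi = 0.98,
                            level_noise_sd = 0.15,
                            surf_temp_mean = 18, surf_temp_amp = 12,
                            surf_temp_peak_doy = 210,
                            strat_temp_drop = 6,
                            strat_depth_mid = 6, strat_width = 1.2,
                            hypolimnion_do_floor = 1, epilimnion_do = 8,
                            strat_onset_doy = 150, strat_end_doy = 280,
                            profile_noise_sd = 0,
                            years = 1995:2020,
                            gap_dates = NULL,
                            seed = 1) {
  cfg <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    cell_size = cell_size,
    basin_min_elev = basin_min_elev, basin_rim_elev = basin_rim_elev,
    basin_roughness_sd = basin_roughness_sd,
    mean_level = mean_level, level_seasonal_amp = level_seasonal_amp,
    level_ar1_phi = level_ar1_phi, level_noise_sd = level_noise_sd,
    surf_temp_mean = surf_temp_mean, surf_temp_amp = surf_temp_amp,
    surf_temp_peak_doy = surf_temp_peak_doy,
    strat_temp_drop = strat_temp_drop,
    strat_depth_mid = strat_depth_mid, strat_width = strat_width,
    hypolimnion_do_floor = hypolimnion_do_floor,
    epilimnion_do = epilimnion_do,
    strat_onset_doy = strat_onset_doy, strat_end_doy = strat_end_doy,
    profile_noise_sd = profile_noise_sd,
    years = as.integer(years), gap_dates = gap_dates,
    seed = as.integer(seed)
  )
  validate_lake_sim_config(cfg)
  structure(cfg, class = "lake_sim_config")
}

validate_lake_sim_config <- function(cfg) {
  if (cfg$grid_rows < 3 || cfg$grid_cols < 3)
    stop("invalid config: grid dimensions must be at least 3x3")
  if (!is.finite(cfg$cell_size) || cfg$cell_size <= 0)
    stop("invalid config: cell_size must be positive")
  if (cfg$basin_min_elev >= cfg$basin_rim_elev)
    stop("invalid config: basin_min_elev must be below basin_rim_elev")
  if (cfg$level_ar1_phi < 0 || cfg$level_ar1_phi >= 1)
    stop("invalid config: level_ar1_phi must lie in [0, 1)")
  if (cfg$hypolimnion_do_floor < 0)
    stop("invalid config: hypolimnion_do_floor must be non-negative")
  if (cfg$hypolimnion_do_floor > cfg$epilimnion_do)
    stop("invalid config: hypolimnion_do_floor exceeds epilimnion_do")
  if (cfg$basin_roughness_sd < 0 || cfg$profile_noise_sd < 0 ||
      cfg$level_noise_sd < 0)
    stop("invalid config: noise sds must be non-negative")
  invisible(cfg)
}

#' Generate a bowl-shaped bathymetric elevation raster
#'
#' An elliptic-paraboloid depression from \code{basin_min_elev} at the grid
#' centre to \code{basin_rim_elev} at the corners, rescaled so the raster
#' attains both extremes exactly, with optional seeded roughness (clamped to
#' the basin's elevation range).  Deterministic for a fixed seed.
#'
#' @param config a \code{\link{lake_sim_config}}.
#' @return a \code{\link{bathymetry_grid}}.
#' @export
generate_bathymetry <- function(config) {
  validate_lake_sim_config(config)
  nr <- config$grid_rows; nc <- config$grid_cols
  # normalized coordinates in [-1, 1] along each axis
  u <- if (nr > 1) 2 * (seq_len(nr) - (nr + 1) / 2) / (nr - 1) else 0
  v <- if (nc > 1) 2 * (seq_len(nc) - (nc + 1) / 2) / (nc - 1) else 0
  q <- outer(u^2, v^2, "+") / 2          # 0 at centre, 1 at corners
  # rescale so min(q) maps to the basin floor even on even-sized grids
  q <- (q - min(q)) / (max(q) - min(q))
  elev <- config$basin_min_elev +
    (config$basin_rim_elev - config$basin_min_elev) * q
  if (config$basin_roughness_sd > 0) {
    noise <- with_seed(derive_seed(config$seed, "roughness"),
                       matrix(stats::rnorm(nr * nc, 0, config$basin_roughness_sd),
                              nr, nc))
    elev <- pmin(pmax(elev + noise, config$basin_min_elev),
                 config$basin_rim_elev)
  }
  bathymetry_grid(elev, cell_size = config$cell_size)
}

#' Generate a daily water-surface-level series
#'
#' level(t) = mean_level + level_seasonal_amp * sin(2*pi*doy/365.25) + e(t),
#' where e(t) is a seeded AR(1) residual with coefficient
#' \code{level_ar1_phi} and innovation sd \code{level_noise_sd} (initialised
#' from its stationary distribution).  Days inside \code{gap_dates} are
#' removed, emulating gauge outages as absent rows.
#'
#' @param config a \code{\link{lake_sim_config}}.
#' @return data.frame (class \code{water_level_series}) with columns
#'   \code{date}, \code{level_m}.
#' @export
generate_water_levels <- function(config) {
  validate_lake_sim_config(config)
  if (length(config$years) == 0) stop("invalid config: years must be non-empty")
  dates <- seq(as.Date(sprintf("%d-01-01", min(config$years))),
               as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% config$years]
  doy <- day_of_year366(dates)
  seasonal <- config$level_seasonal_amp * sin(2 * pi * doy / 365.25)
  n <- length(dates)
  resid <- numeric(n)
  if (config$level_noise_sd > 0) {
    phi <- config$level_ar1_phi
    resid <- with_seed(derive_seed(config$seed, "levels"), {
      e <- numeric(n)
      e[1] <- stats::rnorm(1, 0, config$level_noise_sd / sqrt(1 - phi^2))
      innov <- stats::rnorm(n - 1, 0, config$level_noise_sd)
      for (t in seq_len(n - 1)) e[t + 1] <- phi * e[t] + innov[t]
      e
    })
  }
  out <- data.frame(date = dates,
                    level_m = config$mean_level + seasonal + resid)
  out <- drop_gap_dates(out, config$gap_dates)
  structure(out, class = c("water_level_series", "data.frame"))
}

drop_gap_dates <- function(df, gap_dates) {
  if (is.null(gap_dates) || length(gap_dates) == 0) return(df)
  keep <- rep(TRUE, nrow(df))
  for (g in gap_dates) {
    g <- as.Date(g)
    keep <- keep & !(df$date >= min(g) & df$date <= max(g))
  }
  df[keep, , drop = FALSE]
}

# Seasonal stratification index in [0, 1]: 0 outside the stratified window,
# a half-sine bump inside it, so layers mix smoothly at onset and turnover.
strat_index <- function(doy, onset, end) {
  s <- ifelse(doy > onset & doy < end,
              sin(pi * (doy - onset) / (end - onset)), 0)
  pmax(s, 0)
}

surface_temperature <- function(doy, config) {
  config$surf_temp_mean + config$surf_temp_amp *
    cos(2 * pi * (doy - config$surf_temp_peak_doy) / 365.25)
}

#' Generate daily vertical temperature and DO profiles
#'
#' For each requested date and depth d in 0..10 m:
#' \deqn{T(d) = T_{surf}(t) - \Delta T \, s(t) \,
#'   \mathrm{logistic}((d - z_{mid}) / w)}
#' \deqn{DO(d) = DO_{epi} - (DO_{epi} - DO_{floor}) \, s(t) \,
#'   \mathrm{logistic}((d - z_{mid}) / w)}
#' where s(t) in [0, 1] is the seasonal stratification index.  Outside the
#' stratified window the water column is fully mixed (uniform T and DO);
#' at peak stratification warm oxygenated water overlies a cool hypoxic
#' hypolimnion.  Optional seeded observation noise; DO clamped at 0.
#'
#' @param dates Date vector; must be a subset of \code{levels$date}.
#' @param levels a \code{water_level_series} (dates define availability).
#' @param config a \code{\link{lake_sim_config}}.
#' @return data.frame (class \code{profile_series}) with columns
#'   \code{date}, \code{depth_m}, \code{temp_c}, \code{do_mgl}; all 11
#'   depths present for every date.
#' @export
generate_profiles <- function(dates, levels, config) {
  validate_lake_sim_config(config)
  dates <- as.Date(dates)
  missing <- setdiff(as.character(dates), as.character(levels$date))
  if (length(missing) > 0)
    stop("missing input: no water level for date(s) ", paste(missing[1:min(3, length(missing))], collapse = ", "))
  depths <- 0:10
  grid <- expand.grid(depth_m = depths, date = dates,
                      KEEP.OUT.ATTRS = FALSE)[, c("date", "depth_m")]
  doy <- day_of_year366(grid$date)
  s <- strat_index(doy, config$strat_onset_doy, config$strat_end_doy)
  lgst <- stats::plogis((grid$depth_m - config$strat_depth_mid) / config$strat_width)
  temp <- surface_temperature(doy, config) - config$strat_temp_drop * s * lgst
  dox <- config$epilimnion_do -
    (config$epilimnion_do - config$hypolimnion_do_floor) * s * lgst
  if (config$profile_noise_sd > 0) {
    noise <- with_seed(derive_seed(config$seed, "profiles"),
                       matrix(stats::rnorm(2 * nrow(grid), 0, config$profile_noise_sd),
                              ncol = 2))
    temp <- temp + noise[, 1]
    dox <- pmax(dox + noise[, 2], 0)
  }
  out <- data.frame(date = grid$date, depth_m = grid$depth_m,
                    temp_c = temp, do_mgl = dox)
  structure(out, class = c("profile_series", "data.frame"))
}

.survey_descriptors <- c("cf_total", "cf_lt12", "cf_12_20", "cf_gt20",
                         "wr_lt12", "wr_gt20")

#' Survey effect specification
#'
#' Describes how one winter-gillnet descriptor responds (possibly not at
#' all) to a prior-summer habitat indicator: value(year) = baseline +
#' slope_per_m3 * indicator(year - 1) + Normal(0, noise_sd).
#'
#' @param descriptor one of cf_total, cf_lt12, cf_12_20, cf_gt20 (catch per
#'   net night by size class) or wr_lt12, wr_gt20 (relative weights).
#' @param baseline descriptor value under no habitat effect.
#' @param slope_per_m3 effect per m^3 of the referenced indicator (0 for a
#'   null descriptor).
#' @param indicator_ref list(range =, indicator =) naming the driving
#'   annual indicator; indicator is one of \code{"min_daily_m3"},
#'   \code{"min_avg_14d_m3"}, \code{"min_avg_30d_m3"}.  May be NULL when
#'   slope_per_m3 is 0.
#' @param noise_sd observation noise sd (same units as the descriptor).
#' @return object of class \code{survey_effect_spec}.
#' @export
survey_effect_spec <- function(descriptor, baseline, slope_per_m3 = 0,
                               indicator_ref = NULL, noise_sd = 0) {
  if (!descriptor %in% .survey_descriptors)
    stop("invalid config: unknown descriptor '", descriptor, "'")
  if (noise_sd < 0) stop("invalid config: noise_sd must be non-negative")
  if (slope_per_m3 != 0 && is.null(indicator_ref))
    stop("invalid config: non-zero slope requires an indicator_ref")
  structure(list(descriptor = descriptor, baseline = baseline,
                 slope_per_m3 = slope_per_m3, indicator_ref = indicator_ref,
                 noise_sd = noise_sd),
            class = "survey_effect_spec")
}

#' Default (null) survey effect specifications
#'
#' All six descriptors at field-plausible baselines with zero dependence on
#' habitat: catch per net night around 4--25 fish by size class and
#' relative weights around 88--92.
#'
#' @param noise_scale multiplier on the per-descriptor noise sds.
#' @return named list of \code{\link{survey_effect_spec}}.
#' @export
default_survey_specs <- function(noise_scale = 1) {
  base <- list(cf_total = c(25, 5), cf_lt12 = c(12, 3), cf_12_20 = c(6, 1.5),
               cf_gt20 = c(4, 1), wr_lt12 = c(88, 4), wr_gt20 = c(92, 4))
  out <- lapply(names(base), function(d)
    survey_effect_spec(d, baseline = base[[d]][1],
                       noise_sd = base[[d]][2] * noise_scale))
  names(out) <- names(base)
  out
}

#' Generate an annual fish-survey table
#'
#' Emits one value per (survey year, descriptor) following each
#' \code{\link{survey_effect_spec}}: baseline plus an optional linear effect
#' of the referenced annual habitat indicator from the previous calendar
#' year, plus seeded Gaussian noise.  Years whose previous-year indicator is
#' unavailable keep the baseline-plus-noise value (the effect term is
#' skipped).
#'
#' @param years integer vector of survey years.
#' @param indicators an annual-indicator table
#'   (\code{\link{annual_indicators}}) or NULL when all slopes are zero.
#' @param specs list of \code{\link{survey_effect_spec}}.
#' @param seed integer seed.
#' @return data.frame (class \code{survey_table}) with columns \code{year},
#'   \code{descriptor}, \code{value}.
#' @export
generate_survey <- function(years, indicators = NULL,
                            specs = default_survey_specs(), seed = 1) {
  years <- as.integer(years)
  for (sp in specs)
    if (!inherits(sp, "survey_effect_spec"))
      stop("invalid config: specs must be survey_effect_spec objects")
  rows <- with_seed(derive_seed(seed, "survey"), {
    do.call(rbind, lapply(specs, function(sp) {
      eff <- numeric(length(years))
      if (sp$slope_per_m3 != 0) {
        ref <- sp$indicator_ref
        idx <- indicators[indicators$range == ref$range, , drop = FALSE]
        m <- match(years - 1L, idx$year)
        ind <- idx[[ref$indicator]][m]
        eff <- ifelse(is.na(ind), 0, sp$slope_per_m3 * ind)
      }
      data.frame(year = years, descriptor = sp$descriptor,
                 value = sp$baseline + eff +
                   stats::rnorm(length(years), 0, sp$noise_sd))
    }))
  })
  rownames(rows) <- NULL
  structure(rows, class = c("survey_table", "data.frame"))
}
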