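# Shared fixtures and independent brute-force oracles.

# Small, fast synthetic lake used across module tests.
tiny_config <- function(years = 2000:2001, ...) {
  lake_sim_config(grid_rows = 12, grid_cols = 12,
                  basin_min_elev = 170, basin_rim_elev = 195,
                  years = years, seed = 11, ...)
}

# The 3x3 hand-checked grid from the hypsometry examples.
fixture_grid_3x3 <- function(cell_size = 2) {
  bathymetry_grid(matrix(c(1, 2, 3,
                           2, 3, 4,
                           3, 4, 5), nrow = 3, byrow = TRUE),
                  cell_size = cell_size)
}

# Brute-force oracle: submerged area by direct per-cell scan.
oracle_area <- function(grid, z) {
  sum(grid$elevations <= z, na.rm = TRUE) * grid$cell_size^2
}

# Brute-force oracle: daily suitable volume by per-plane cell counting,
# depths ascending (same summation order as the implementation so exact
# equality is meaningful).
oracle_daily_volume <- function(grid, level, profile, range, scenario,
                                depths = 0:10) {
  contrib <- vapply(depths, function(d) {
    row <- profile[profile$depth_m == d, ]
    suit <- is_suitable(row$temp_c, row$do_mgl, range, scenario)
    count <- sum(grid$elevations <= level - d, na.rm = TRUE)
    count * grid$cell_size^2 * as.numeric(suit)
  }, numeric(1))
  sum(contrib)
}

# Closed-form OLS oracle (normal equations + t distribution), independent
# of stats::lm.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept,
       p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Random small elevation grid (optionally with nodata holes).
random_grid <- function(nr = NULL, nc = NULL, nodata_frac = 0) {
  nr <- nr %||% sample(3:10, 1)
  nc <- nc %||% sample(3:10, 1)
  m <- matrix(stats::runif(nr * nc, 160, 200), nr, nc)
  if (nodata_frac > 0) {
    holes <- stats::runif(nr * nc) < nodata_frac
    if (all(holes)) holes[1] <- FALSE
    m[holes] <- NA
  }
  bathymetry_grid(m, cell_size = stats::runif(1, 1, 500))
}

# Single-date random profile over depths 0..10.
random_profile <- function(date = as.Date("2000-07-15")) {
  data.frame(date = date, depth_m = 0:10,
             temp_c = stats::runif(11, 15, 33),
             do_mgl = stats::runif(11, 0, 9))
}

# Hand-built daily volume table (plain data.frame with the right columns).
volumes_table <- function(dates, values, range = "r", scenario = "both") {
  data.frame(date = as.Date(dates), range = range, scenario = scenario,
             volume_m3 = values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
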