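# Seeded synthetic-lake generators: geometry, level dynamics, stratified
# profiles, survey metrics.

test_that("bathymetry is a bowl attaining both elevation extremes", {
  cfg <- lake_sim_config(grid_rows = 3, grid_cols = 3,
                         basin_min_elev = 180, basin_rim_elev = 190,
                         years = 2000)
  g <- generate_bathymetry(cfg)
  expect_equal(g$elevations[2, 2], 180)
  expect_equal(g$elevations[1, 1], 190)
  expect_equal(g$elevations[3, 3], 190)
  # monotone non-decreasing along rays from the centre
  expect_true(all(diff(g$elevations[2, 2:3]) >= 0))
  expect_true(all(diff(g$elevations[2:1, 2]) <= 0) ||
              all(diff(rev(g$elevations[1:2, 2])) >= 0))

  cfg50 <- lake_sim_config(grid_rows = 50, grid_cols = 50,
                           basin_min_elev = 178, basin_rim_elev = 195,
                           years = 2000)
  g50 <- generate_bathymetry(cfg50)
  expect_equal(min(g50$elevations), 178, tolerance = 1e-9)
  expect_equal(max(g50$elevations), 195, tolerance = 1e-9)
})

test_that("generators are deterministic for a fixed seed", {
  cfg <- tiny_config(basin_roughness_sd = 0.5, profile_noise_sd = 0.1)
  expect_identical(generate_bathymetry(cfg)$elevations,
                   generate_bathymetry(cfg)$elevations)
  l1 <- generate_water_levels(cfg)
  l2 <- generate_water_levels(cfg)
  expect_identical(l1, l2)
  d <- l1$date[1:20]
  expect_identical(generate_profiles(d, l1, cfg),
                   generate_profiles(d, l1, cfg))
  ind <- data.frame(year = 1999:2001, range = "r",
                    min_daily_m3 = c(1, 2, 3) * 1e6)
  sp <- list(survey_effect_spec("cf_total", 25, slope_per_m3 = 1e-6,
                                indicator_ref = list(range = "r",
                                                     indicator = "min_daily_m3"),
                                noise_sd = 2))
  expect_identical(generate_survey(2000:2002, ind, sp, seed = 5),
                   generate_survey(2000:2002, ind, sp, seed = 5))
})

test_that("invalid configurations are rejected", {
  expect_error(lake_sim_config(grid_rows = 2), "3x3")
  expect_error(lake_sim_config(cell_size = 0), "cell_size")
  expect_error(lake_sim_config(basin_min_elev = 200, basin_rim_elev = 190),
               "basin_min_elev")
  expect_error(lake_sim_config(level_ar1_phi = 1), "ar1")
  expect_error(lake_sim_config(hypolimnion_do_floor = -1), "do_floor")
  expect_error(lake_sim_config(years = integer(0)) |> generate_water_levels(),
               "years")
})

test_that("degenerate water levels equal the mean exactly", {
  cfg <- tiny_config(level_seasonal_amp = 0, level_noise_sd = 0)
  lv <- generate_water_levels(cfg)
  expect_true(all(lv$level_m == cfg$mean_level))
})

test_that("noise-free levels stay within the seasonal envelope", {
  cfg <- tiny_config(level_noise_sd = 0, level_seasonal_amp = 1.7)
  lv <- generate_water_levels(cfg)
  expect_true(all(abs(lv$level_m - cfg$mean_level) <= 1.7 + 1e-12))
})

test_that("level residuals recover the AR(1) coefficient", {
  cfg <- lake_sim_config(grid_rows = 5, grid_cols = 5,
                         years = 1991:2010, level_seasonal_amp = 0,
                         level_ar1_phi = 0.9, level_noise_sd = 0.05,
                         seed = 3)
  lv <- generate_water_levels(cfg)
  resid <- lv$level_m - cfg$mean_level
  rho <- stats::cor(resid[-length(resid)], resid[-1])
  expect_lt(abs(rho - 0.9), 0.05)
})

test_that("gap dates are absent rows, not sentinels", {
  cfg <- lake_sim_config(grid_rows = 5, grid_cols = 5, years = 2014:2017,
                         gap_dates = list(c("2015-01-01", "2016-12-31")))
  lv <- generate_water_levels(cfg)
  yr <- format(lv$date, "%Y")
  expect_false(any(yr %in% c("2015", "2016")))
  expect_true(all(c("2014", "2017") %in% yr))
})

test_that("winter profiles are fully mixed, summer profiles stratified", {
  cfg <- tiny_config()
  lv <- generate_water_levels(cfg)
  pr <- generate_profiles(lv$date, lv, cfg)
  expect_equal(nrow(pr), length(lv$date) * 11)

  jan <- pr[pr$date == as.Date("2000-01-15"), ]
  expect_true(all(jan$temp_c == jan$temp_c[1]))
  expect_true(all(jan$do_mgl == jan$do_mgl[1]))

  # noise off: temperature and DO non-increasing in depth on every date
  byd <- split(pr, pr$date)
  mono <- vapply(byd, function(p) {
    p <- p[order(p$depth_m), ]
    all(diff(p$temp_c) <= 1e-12) && all(diff(p$do_mgl) <= 1e-12)
  }, logical(1))
  expect_true(all(mono))

  aug <- pr[pr$date == as.Date("2000-08-05"), ]
  expect_gt(aug$temp_c[1] - aug$temp_c[11], 3)  # thermocline present
  expect_lt(min(aug$do_mgl), 3)                 # hypolimnetic depletion
})

test_that("surface temperature respects the seasonal envelope", {
  cfg <- tiny_config(surf_temp_mean = 18, surf_temp_amp = 12)
  lv <- generate_water_levels(cfg)
  pr <- generate_profiles(lv$date, lv, cfg)
  expect_lte(max(pr$temp_c[pr$depth_m == 0]), 30 + 1e-12)
})

test_that("profiles require a level for every requested date", {
  cfg <- tiny_config()
  lv <- generate_water_levels(cfg)
  expect_error(generate_profiles(as.Date("1990-01-01"), lv, cfg),
               "missing input")
})

test_that("null survey specs give constant descriptors at baseline", {
  specs <- default_survey_specs(noise_scale = 0)
  sv <- generate_survey(2000:2010, indicators = NULL, specs = specs, seed = 2)
  expect_setequal(unique(sv$descriptor),
                  c("cf_total", "cf_lt12", "cf_12_20", "cf_gt20",
                    "wr_lt12", "wr_gt20"))
  for (d in unique(sv$descriptor)) {
    v <- sv$value[sv$descriptor == d]
    expect_true(all(v == v[1]))
  }
  expect_error(survey_effect_spec("cf_huge", 1), "descriptor")
})

test_that("survey effect terms follow the prior-year indicator", {
  ind <- data.frame(year = 1999:2009, range = "r",
                    min_daily_m3 = seq(1e6, 11e6, by = 1e6))
  sp <- list(survey_effect_spec("cf_gt20", baseline = 4,
                                slope_per_m3 = 2e-6,
                                indicator_ref = list(range = "r",
                                                     indicator = "min_daily_m3"),
                                noise_sd = 0))
  sv <- generate_survey(2000:2010, ind, sp, seed = 1)
  expect_equal(sv$value, 4 + 2e-6 * seq(1e6, 11e6, by = 1e6))
  # years with no prior indicator fall back to baseline
  sv2 <- generate_survey(1999, ind, sp, seed = 1)
  expect_equal(sv2$value, 4)
})

test_that("an injected effect is recoverable by regression on the matching indicator", {
  # signal sd = 3x noise sd over 23 years: the regression should recover
  # the slope sign essentially always
  set.seed(21)
  ind_years <- 1994:2016
  ind_vals <- stats::runif(length(ind_years), 0, 1e8)
  ind <- data.frame(year = ind_years, range = "r", min_daily_m3 = ind_vals)
  noise_sd <- 1
  slope <- 3 * noise_sd / stats::sd(ind_vals)
  sp <- list(survey_effect_spec("cf_total", 25, slope_per_m3 = slope,
                                indicator_ref = list(range = "r",
                                                     indicator = "min_daily_m3"),
                                noise_sd = noise_sd))
  hits <- vapply(seq_len(200), function(i) {
    sv <- generate_survey(1995:2017, ind, sp, seed = 1000 + i)
    x <- ind$min_daily_m3[match(sv$year - 1, ind$year)]
    fit <- stats::lm(sv$value ~ x)
    coef(fit)[2] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
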