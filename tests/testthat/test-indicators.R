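# Climatology, annual pulse/press indicators, autocorrelation.

test_that("climatology reduces to two-point arithmetic across years", {
  d1 <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
  d2 <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  v <- rbind(volumes_table(d1, 10), volumes_table(d2, 20))
  cl <- seasonal_climatology(v)
  # Feb 29 exists only in the 2000 series
  leap <- cl$doy == 60
  expect_true(all(cl$mean_m3[!leap] == 15) && cl$mean_m3[leap] == 10)
  expect_equal(unique(cl$sd_m3[!leap]), stats::sd(c(10, 20)))
  expect_true(all(cl$n[!leap] == 2) && cl$n[leap] == 1)

  # identical years: mean is the series, sd 0
  # 2000 is leap, 2001 is not: align values by calendar day
  v2 <- rbind(volumes_table(d1, seq_along(d1)),
              volumes_table(d2, c(1:59, 61:366)))
  cl2 <- seasonal_climatology(v2)
  expect_true(all(cl2$sd_m3 == 0))

  # single year reproduces itself with sd 0
  cl3 <- seasonal_climatology(volumes_table(d1, seq_along(d1)))
  expect_equal(cl3$mean_m3[order(cl3$doy)], seq_along(d1))
  expect_true(all(cl3$sd_m3 == 0) && all(cl3$n == 1))

  # permutation invariance over years
  cl4 <- seasonal_climatology(rbind(volumes_table(d2, 20),
                                    volumes_table(d1, 10)))
  expect_equal(cl4, cl)
  expect_message(seasonal_climatology(v[0, , drop = FALSE]), "empty")
})

test_that("Feb 29 is its own climatological day", {
  v <- rbind(volumes_table("2000-02-29", 7), volumes_table("2001-03-01", 9))
  cl <- seasonal_climatology(v)
  expect_equal(cl$doy[cl$mean_m3 == 7], 60)
  expect_equal(cl$doy[cl$mean_m3 == 9], 61)
  expect_true(all(cl$n == 1))
})

test_that("annual minimum is the worst observed day", {
  v <- volumes_table(c("2000-06-01", "2000-06-02", "2000-06-03"), c(5, 3, 7))
  expect_equal(annual_min(v, 2000, "r"), 3)
  v0 <- volumes_table(c("2000-06-01", "2000-06-02"), c(4, 0))
  expect_equal(annual_min(v0, 2000, "r"), 0)
  expect_true(is.na(annual_min(v, 1999, "r")))
})

test_that("rolling minimum average enumerates complete forward windows", {
  v <- volumes_table(seq(as.Date("2000-03-01"), by = "day", length.out = 6),
                     1:6)
  expect_equal(rolling_min_average(v, 2000, "r", window = 2), 1.5)
  expect_equal(rolling_min_average(v, 2000, "r", window = 1),
               annual_min(v, 2000, "r"))
  # constant series: any window returns the constant
  vc <- volumes_table(seq(as.Date("2000-01-01"), by = "day", length.out = 40),
                      7)
  expect_equal(rolling_min_average(vc, 2000, "r", 14), 7)
  # no complete window of consecutive observed days
  vg <- volumes_table(c("2000-01-01", "2000-01-03"), c(1, 2))
  expect_true(is.na(rolling_min_average(vg, 2000, "r", 2)))
})

test_that("rolling windows match exhaustive enumeration on a full year", {
  set.seed(303)
  days <- seq(as.Date("2003-01-01"), as.Date("2003-12-31"), by = "day")
  x <- stats::runif(length(days), 0, 1e9)
  v <- volumes_table(days, x)
  for (w in c(14, 30)) {
    brute <- min(vapply(seq_len(length(x) - w + 1),
                        function(i) mean(x[i:(i + w - 1)]), numeric(1)))
    expect_equal(rolling_min_average(v, 2003, "r", w), brute)
  }
  expect_equal(annual_min(v, 2003, "r"), min(x))
})

test_that("annual indicators satisfy the pulse <= press ordering", {
  cfg <- tiny_config()
  lv <- generate_water_levels(cfg)
  pr <- generate_profiles(lv$date, lv, cfg)
  curve <- build_hypsometric_curve(generate_bathymetry(cfg))
  vols <- volume_series(curve, lv, pr)
  ind <- annual_indicators(vols)
  expect_equal(nrow(ind), 2 * 3)  # 2 years x 3 ranges
  ok <- !is.na(ind$min_avg_14d_m3)
  expect_true(all(ind$min_daily_m3[ok] <= ind$min_avg_14d_m3[ok] + 1e-9))
  expect_true(all(ind$min_daily_m3[ok] <= ind$min_avg_30d_m3[ok] + 1e-9))
  expect_true(all(ind$coverage == 1) && !any(ind$low_coverage))

  # rerun is deterministic: indicators are a pure function of volumes
  expect_identical(ind, annual_indicators(vols))

  # a summer-long gap flags the year low-coverage
  gap <- format(lv$date, "%Y") == "2001" &
    as.integer(format(lv$date, "%m")) %in% 6:10
  vols2 <- volume_series(curve, lv[!gap, ], pr)
  ind2 <- annual_indicators(vols2)
  expect_true(all(ind2$low_coverage[ind2$year == 2001]))
  expect_false(any(ind2$low_coverage[ind2$year == 2000]))
})

test_that("lag-1 autocorrelation uses consecutive pairs only", {
  n <- 100
  v <- volumes_table(seq(as.Date("2000-01-01"), by = "day", length.out = n),
                     rep(c(1, -1), n / 2))
  expect_equal(lag1_autocorrelation(v, "r"), -1, tolerance = 1e-9)

  vc <- volumes_table(seq(as.Date("2000-01-01"), by = "day", length.out = 10),
                      5)
  expect_warning(rho <- lag1_autocorrelation(vc, "r"), "zero-variance")
  expect_true(is.na(rho))

  # pairs spanning a gap are excluded: an every-other-day series has no
  # consecutive pairs at all
  v2 <- volumes_table(seq(as.Date("2000-01-01"), by = "2 days",
                          length.out = 50), stats::runif(50))
  expect_error(lag1_autocorrelation(v2, "r"), "consecutive")
})

test_that("AR(1) series recovers its coefficient", {
  set.seed(304)
  n <- 5000
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  # spread over consecutive days across years; estimator ignores Dec31->Jan1
  # only where dates are non-consecutive, which never happens here
  v <- volumes_table(seq(as.Date("1990-01-01"), by = "day", length.out = n),
                     x)
  expect_lt(abs(lag1_autocorrelation(v, "r") - 0.9), 0.03)
})
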