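# Reductions of the daily habitat-volume series: day-of-year climatology,
# lag-1 autocorrelation, and the annual pulse/press disturbance indicators
# feeding the regression screen.

#' Day-of-year climatology of habitat volume
#'
#' Groups daily volumes by calendar day of year (366-day calendar, Feb 29
#' its own day) and returns the across-year mean and sample standard
#' deviation per (day, range, scenario).  sd is 0 where only one year
#' contributes.
#'
#' @param volumes a \code{daily_habitat_volume} table.
#' @return data.frame with columns \code{doy}, \code{range},
#'   \code{scenario}, \code{mean_m3}, \code{sd_m3}, \code{n}.
#' @export
seasonal_climatology <- function(volumes) {
  if (nrow(volumes) == 0) {
    message("seasonal_climatology: empty input, returning empty climatology")
    return(data.frame(doy = integer(), range = character(),
                      scenario = character(), mean_m3 = numeric(),
                      sd_m3 = numeric(), n = integer()))
  }
  doy <- day_of_year366(volumes$date)
  key <- interaction(doy, volumes$range, volumes$scenario, drop = TRUE,
                     sep = "\x1f")
  agg <- function(f) tapply(volumes$volume_m3, key, f)
  mu <- agg(mean)
  sdv <- agg(function(x) if (length(x) > 1) stats::sd(x) else 0)
  n <- agg(length)
  parts <- do.call(rbind, strsplit(names(mu), "\x1f", fixed = TRUE))
  out <- data.frame(doy = as.integer(parts[, 1]), range = parts[, 2],
                    scenario = parts[, 3], mean_m3 = as.numeric(mu),
                    sd_m3 = as.numeric(sdv), n = as.integer(n))
  out <- out[order(out$range, out$scenario, out$doy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Daily volume vector for one year/range/scenario placed on the full
# calendar (NA where unobserved).
year_calendar_vector <- function(volumes, year, range, scenario = "both") {
  sel <- volumes[volumes$range == range & volumes$scenario == scenario, ,
                 drop = FALSE]
  sel <- sel[as.integer(format(sel$date, "%Y")) == year, , drop = FALSE]
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  v <- rep(NA_real_, length(days))
  v[match(as.character(sel$date), as.character(days))] <- sel$volume_m3
  v
}

#' Yearly minimum daily habitat volume (pulse disturbance)
#'
#' The minimum over the year's observed days: the single worst day of the
#' squeeze.
#'
#' @param volumes a \code{daily_habitat_volume} table.
#' @param year calendar year.
#' @param range range label.
#' @param scenario stressor scenario (indicators use \code{"both"}).
#' @return minimum volume in m^3, or NA if the year has no observed days.
#' @export
annual_min <- function(volumes, year, range, scenario = "both") {
  v <- year_calendar_vector(volumes, year, range, scenario)
  if (all(is.na(v))) return(NA_real_)
  min(v, na.rm = TRUE)
}

#' Minimum rolling-window mean volume (press disturbance)
#'
#' Forward-looking windows of \code{window} consecutive calendar days start
#' at each day of the year and must lie wholly within it; windows containing
#' any unobserved day are discarded.  Returns the minimum window mean --
#' the worst sustained squeeze of that length.
#'
#' @inheritParams annual_min
#' @param window window length in days (>= 1).
#' @return minimum window-mean volume in m^3, or NA when no complete window
#'   of observed days exists.
#' @export
rolling_min_average <- function(volumes, year, range, window,
                                scenario = "both") {
  stopifnot(window >= 1)
  v <- year_calendar_vector(volumes, year, range, scenario)
  if (length(v) < window) return(NA_real_)
  # an anonymous wrapper keeps zoo off its cumsum fast path, whose roundoff
  # can push all-zero windows slightly negative
  means <- zoo::rollapply(v, width = window, FUN = function(x) mean(x),
                          align = "left", fill = NA)
  if (all(is.na(means))) return(NA_real_)
  min(means, na.rm = TRUE)
}

#' Annual pulse/press habitat indicators
#'
#' Per (year, range), under the both-stressor scenario: the yearly minimum
#' daily volume and the minimum 14- and 30-day rolling-mean volumes, plus
#' the fraction of calendar days observed and a low-coverage flag raised
#' when fewer than \code{min_season_coverage} of June--October days (the
#' squeeze season) were observed.  Low-coverage years are excluded from the
#' regression screen.
#'
#' @param volumes a \code{daily_habitat_volume} table.
#' @param windows rolling-window lengths in days.
#' @param scenario stressor scenario, default \code{"both"}.
#' @param min_season_coverage minimum observed fraction of Jun--Oct days.
#' @return data.frame (class \code{annual_indicators}) with columns
#'   \code{year}, \code{range}, \code{min_daily_m3}, one
#'   \code{min_avg_<w>d_m3} per window, \code{coverage},
#'   \code{low_coverage}.
#' @export
annual_indicators <- function(volumes, windows = c(14, 30),
                              scenario = "both",
                              min_season_coverage = 0.5) {
  sel <- volumes[volumes$scenario == scenario, , drop = FALSE]
  if (nrow(sel) == 0) stop("no volumes under scenario '", scenario, "'")
  years <- sort(unique(as.integer(format(sel$date, "%Y"))))
  ranges <- unique(sel$range)
  rows <- list(); k <- 1
  for (rg in ranges) {
    for (yr in years) {
      v <- year_calendar_vector(sel, yr, rg, scenario)
      days <- seq(as.Date(sprintf("%d-01-01", yr)),
                  as.Date(sprintf("%d-12-31", yr)), by = "day")
      season <- as.integer(format(days, "%m")) %in% 6:10
      row <- data.frame(year = yr, range = rg,
                        min_daily_m3 = if (all(is.na(v))) NA_real_
                                       else min(v, na.rm = TRUE),
                        coverage = mean(!is.na(v)),
                        low_coverage = mean(!is.na(v[season])) <
                          min_season_coverage)
      for (w in windows)
        row[[sprintf("min_avg_%dd_m3", w)]] <-
          rolling_min_average(sel, yr, rg, w, scenario)
      rows[[k]] <- row; k <- k + 1
    }
  }
  out <- do.call(rbind, rows)
  cols <- c("year", "range", "min_daily_m3",
            sprintf("min_avg_%dd_m3", windows), "coverage", "low_coverage")
  out <- out[, cols]
  rownames(out) <- NULL
  structure(out, class = c("annual_indicators", "data.frame"))
}

#' Lag-1 autocorrelation of the daily volume series
#'
#' Pearson correlation between volumes on consecutive observed dates; pairs
#' spanning a data gap are excluded so gaps do not fabricate spurious lags.
#' A zero-variance series returns NA (undefined) with a warning.
#'
#' @param volumes a \code{daily_habitat_volume} table.
#' @param range range label.
#' @param scenario stressor scenario, default \code{"both"}.
#' @return lag-1 autocorrelation estimate, or NA.
#' @export
lag1_autocorrelation <- function(volumes, range, scenario = "both") {
  sel <- volumes[volumes$range == range & volumes$scenario == scenario, ,
                 drop = FALSE]
  sel <- sel[order(sel$date), , drop = FALSE]
  consec <- which(diff(as.integer(sel$date)) == 1L)
  if (length(consec) < 3)
    stop("insufficient data: need at least 3 consecutive-day pairs")
  x <- sel$volume_m3[consec]
  y <- sel$volume_m3[consec + 1]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("lag1_autocorrelation undefined for zero-variance series")
    return(NA_real_)
  }
  stats::cor(x, y)
}
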