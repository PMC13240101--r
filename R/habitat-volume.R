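# Daily suitable-habitat volume: trait thresholds applied to each 1 m depth
# plane, plane areas looked up on the hypsometric curve, and summed over the
# top of the water column.

#' Temperature-oxygen squeeze range
#'
#' A pair of trait thresholds for the fish: an upper temperature limit and a
#' dissolved-oxygen floor.  Both bounds are inclusive (temp <= t_max,
#' do >= do_min counts as suitable).
#'
#' @param name short label used in outputs.
#' @param t_max upper temperature limit, degC.
#' @param do_min minimum dissolved oxygen, mg/L (>= 0).
#' @return object of class \code{squeeze_range}.
#' @export
squeeze_range <- function(name, t_max, do_min = 3) {
  if (do_min < 0) stop("invalid range: do_min must be non-negative")
  structure(list(name = name, t_max = t_max, do_min = do_min),
            class = "squeeze_range")
}

#' The three striped-bass squeeze ranges
#'
#' Upper thermal preference (25 degC), upper thermal tolerance (28 degC),
#' and acute upper thermal tolerance (30 degC), each with a 3 mg/L DO floor.
#'
#' @return named list of \code{\link{squeeze_range}}.
#' @export
default_squeeze_ranges <- function() {
  list(pref25 = squeeze_range("pref25", 25, 3),
       tol28 = squeeze_range("tol28", 28, 3),
       acute30 = squeeze_range("acute30", 30, 3))
}

#' Stressor scenarios
#'
#' Which stressors constrain suitability: \code{"none"} (total water volume
#' control), \code{"do_only"}, \code{"temp_only"}, or \code{"both"}.
#'
#' @return character vector of the four scenario names.
#' @export
stressor_scenarios <- function() c("none", "do_only", "temp_only", "both")

#' Is a depth plane suitable?
#'
#' Applies the squeeze-range thresholds under a stressor scenario.
#' Vectorised over \code{temp} and \code{do}.  NA temperature or DO makes a
#' plane unsuitable under any scenario that consults the missing value
#' (callers count these as missing-data planes rather than erroring).
#'
#' @param temp temperature(s), degC.
#' @param do dissolved oxygen, mg/L.
#' @param range a \code{\link{squeeze_range}}.
#' @param scenario one of \code{\link{stressor_scenarios}}.
#' @return logical vector.
#' @export
is_suitable <- function(temp, do, range, scenario = "both") {
  scenario <- match.arg(scenario, stressor_scenarios())
  temp_ok <- !is.na(temp) & temp <= range$t_max
  do_ok <- !is.na(do) & do >= range$do_min
  switch(scenario,
         none = rep(TRUE, length(temp)),
         temp_only = temp_ok,
         do_only = do_ok,
         both = temp_ok & do_ok)
}

#' Suitable habitat volume for a single date
#'
#' For each 1 m depth plane d in \code{depths}, the plane contributes
#' area_at_elevation(curve, level - d) x 1 m if its temperature and DO pass
#' \code{\link{is_suitable}}, else 0; the daily volume is the sum over
#' planes.  Planes below the basin floor contribute zero area.
#'
#' @param curve a \code{\link{hypsometric_curve}}.
#' @param level water-surface level, m AMSL.
#' @param profile single-date data.frame with columns \code{depth_m},
#'   \code{temp_c}, \code{do_mgl} covering every depth in \code{depths}.
#' @param range a \code{\link{squeeze_range}}.
#' @param scenario one of \code{\link{stressor_scenarios}}.
#' @param depths integer depth planes (m below surface); the default 0:10
#'   follows the 1 m profile sampling of the top of the water column.
#' @return volume in m^3.
#' @export
daily_volume <- function(curve, level, profile, range, scenario = "both",
                         depths = 0:10) {
  m <- match(depths, profile$depth_m)
  if (any(is.na(m)))
    stop("incomplete profile: missing depth(s) ",
         paste(depths[is.na(m)], collapse = ", "))
  suit <- is_suitable(profile$temp_c[m], profile$do_mgl[m], range, scenario)
  areas <- area_at_elevation(curve, level - depths)
  sum(areas * as.numeric(suit))
}

#' Daily suitable-habitat volume series
#'
#' Evaluates \code{\link{daily_volume}} for every date present in both the
#' level and profile series, for every squeeze range and stressor scenario.
#' Dates missing either input are skipped (recorded in the
#' \code{skipped_dates} attribute); NA profile planes are counted in the
#' \code{n_missing_planes} attribute.
#'
#' @param curve a \code{\link{hypsometric_curve}}.
#' @param levels a \code{water_level_series} (columns date, level_m).
#' @param profiles a \code{profile_series} (columns date, depth_m, temp_c,
#'   do_mgl).
#' @param ranges list of \code{\link{squeeze_range}} (default the three
#'   striped-bass ranges).
#' @param scenarios subset of \code{\link{stressor_scenarios}}.
#' @param depths integer depth planes, default 0:10.
#' @return data.frame (class \code{daily_habitat_volume}) with columns
#'   \code{date}, \code{range}, \code{scenario}, \code{volume_m3}.
#' @export
volume_series <- function(curve, levels, profiles,
                          ranges = default_squeeze_ranges(),
                          scenarios = stressor_scenarios(),
                          depths = 0:10) {
  stopifnot(length(ranges) > 0)
  scenarios <- match.arg(scenarios, stressor_scenarios(), several.ok = TRUE)
  common <- intersect(as.character(levels$date), as.character(profiles$date))
  if (length(common) == 0) stop("no overlap between level and profile dates")
  skipped <- union(setdiff(as.character(levels$date), common),
                   setdiff(as.character(profiles$date), common))
  dates <- as.Date(sort(common))

  lvl <- levels$level_m[match(as.character(dates), as.character(levels$date))]
  prof <- profiles[as.character(profiles$date) %in% common, , drop = FALSE]
  prof <- prof[prof$depth_m %in% depths, , drop = FALSE]
  di <- match(as.character(prof$date), as.character(dates))
  if (any(tabulate(di, nbins = length(dates)) != length(depths)))
    stop("incomplete profile: some dates lack the full depth set")
  # plane areas: one lookup per (date, depth)
  plane_area <- area_at_elevation(curve, lvl[di] - prof$depth_m)
  n_missing <- sum(is.na(prof$temp_c) | is.na(prof$do_mgl))

  out <- list(); k <- 1
  for (rn in seq_along(ranges)) {
    rg <- ranges[[rn]]
    rg_name <- names(ranges)[rn] %||% rg$name
    if (is.null(rg_name) || rg_name == "") rg_name <- rg$name
    for (sc in scenarios) {
      suit <- is_suitable(prof$temp_c, prof$do_mgl, rg, sc)
      vol <- rowsum(plane_area * as.numeric(suit), group = di)
      out[[k]] <- data.frame(date = dates, range = rg_name, scenario = sc,
                             volume_m3 = as.numeric(vol))
      k <- k + 1
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res,
            class = c("daily_habitat_volume", "data.frame"),
            skipped_dates = skipped,
            n_missing_planes = n_missing)
}
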