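# Penalized additive trend model for daily habitat volume: smooths of the
# one-day-lagged volume, a cyclic day-of-year seasonal term, a long-term
# fractional-year term, and water level.  Fitted with mgcv.

#' Build the GAM design table
#'
#' One row per date carrying the day's volume (response), the previous
#' calendar day's volume (lag-1 smooth, absorbing the series' strong
#' temporal autocorrelation), the day of year, the fractional-year date,
#' and the water level.  Rows whose previous day is unobserved, or that
#' lack a level observation, are dropped.
#'
#' @param volumes a \code{daily_habitat_volume} table.
#' @param levels a \code{water_level_series}.
#' @param range range label to model.
#' @param scenario stressor scenario, default \code{"both"}.
#' @return data.frame with columns \code{date}, \code{habitat_t},
#'   \code{habitat_lag1}, \code{day_of_year}, \code{date_frac},
#'   \code{water_level}.
#' @export
prepare_gam_table <- function(volumes, levels, range, scenario = "both") {
  sel <- volumes[volumes$range == range & volumes$scenario == scenario, ,
                 drop = FALSE]
  sel <- sel[order(sel$date), , drop = FALSE]
  prev <- match(as.character(sel$date - 1), as.character(sel$date))
  lvl <- levels$level_m[match(as.character(sel$date),
                              as.character(levels$date))]
  keep <- !is.na(prev) & !is.na(lvl)
  out <- data.frame(date = sel$date,
                    habitat_t = sel$volume_m3,
                    habitat_lag1 = sel$volume_m3[prev],
                    day_of_year = day_of_year366(sel$date),
                    date_frac = date_fraction(sel$date),
                    water_level = lvl)[keep, , drop = FALSE]
  if (nrow(out) < 30)
    stop("insufficient data: fewer than 30 usable rows for the GAM")
  rownames(out) <- NULL
  out
}

.gam_terms <- c(habitat_lag1 = "s(habitat_lag1)",
                day_of_year = "s(day_of_year)",
                date_frac = "s(date_frac)",
                water_level = "s(water_level)")

#' Fit the habitat-squeeze GAM
#'
#' \deqn{Habitat_t = \beta_0 + f(Habitat_{t-1}) + f(DayOfYear_t) +
#'   f(Date_t) + f(WaterLevel_t) + \epsilon_t}
#' Gaussian errors, identity link.  The day-of-year smooth uses a cyclic
#' cubic regression spline (knots at days 1 and 366, so the seasonal effect
#' is continuous across the year boundary); the other smooths are
#' thin-plate regression splines.  Fitted with \code{mgcv::bam} under fast
#' REML (falling back to \code{mgcv::gam}/REML if the design is too small
#' for discretization).  Predictors with too few distinct values for a
#' smooth are dropped with a degenerate-term warning and reported with
#' edf 0.
#'
#' @param rows design table from \code{\link{prepare_gam_table}}.
#' @param k named basis dimensions: \code{lag}, \code{doy}, \code{date},
#'   \code{level}.  Day of year defaults to a richer basis because the
#'   seasonal contraction is the sharpest feature.
#' @param discrete passed to \code{mgcv::bam}.
#' @return object of class \code{squeeze_gam}: the fitted model plus a
#'   per-term table (edf, F, p-value), \code{r_sq}, \code{resid_sd},
#'   residual lag-1 autocorrelation, and centred partial-effect curves on
#'   200-point grids.
#' @export
fit_squeeze_gam <- function(rows,
                            k = c(lag = 10, doy = 20, date = 10, level = 10),
                            discrete = TRUE) {
  if (nrow(rows) < 30) stop("insufficient data: need at least 30 rows")
  if (any(k < 3)) stop("basis dimensions must be at least 3")
  if (stats::sd(rows$habitat_t) == 0) {
    # constant response: nothing to smooth; report every term as degenerate
    warning("degenerate fit: constant response")
    vars <- c("habitat_lag1", "day_of_year", "date_frac", "water_level")
    return(structure(list(
      model = NULL,
      terms = data.frame(term = vars, edf = 0, f = NA_real_,
                         p_value = NA_real_),
      r_sq = NA_real_, resid_sd = 0, resid_acf1 = NA_real_,
      n = nrow(rows), dropped = vars, partial_effects = NULL),
      class = "squeeze_gam"))
  }
  kmap <- c(habitat_lag1 = unname(k["lag"]), day_of_year = unname(k["doy"]),
            date_frac = unname(k["date"]), water_level = unname(k["level"]))
  terms <- character(); dropped <- character()
  for (v in names(kmap)) {
    nu <- length(unique(rows[[v]]))
    kv <- min(kmap[[v]], nu - 1)
    if (nu < 4 || kv < 3) {
      warning("degenerate term: '", v, "' has too few distinct values; dropped")
      dropped <- c(dropped, v)
      next
    }
    terms <- c(terms,
               if (v == "day_of_year")
                 sprintf("s(day_of_year, bs = 'cc', k = %d)", kv)
               else sprintf("s(%s, k = %d)", v, kv))
  }
  if (length(terms) == 0) stop("no usable smooth terms")
  fml <- stats::as.formula(paste("habitat_t ~", paste(terms, collapse = " + ")))
  knots <- if ("day_of_year" %in% dropped) NULL else
    list(day_of_year = c(1, 366))
  fit <- tryCatch(
    mgcv::bam(fml, data = rows, method = "fREML", discrete = discrete,
              knots = knots),
    error = function(e)
      mgcv::gam(fml, data = rows, method = "REML", knots = knots))
  sm <- summary(fit)
  st <- sm$s.table
  term_tab <- data.frame(
    term = sub("^s\\(([^,)]+)\\)$", "\\1", rownames(st)),
    edf = st[, "edf"], f = st[, "F"], p_value = st[, "p-value"],
    row.names = NULL)
  if (length(dropped) > 0)
    term_tab <- rbind(term_tab,
                      data.frame(term = dropped, edf = 0, f = NA_real_,
                                 p_value = NA_real_))
  r_sq <- sm$r.sq
  if (!is.finite(r_sq)) r_sq <- NA_real_
  res <- stats::residuals(fit)
  resid_acf1 <- if (stats::sd(res) > 0)
    stats::cor(res[-length(res)], res[-1]) else NA_real_
  structure(list(model = fit, terms = term_tab, r_sq = r_sq,
                 resid_sd = stats::sd(res), resid_acf1 = resid_acf1,
                 n = nrow(rows), dropped = dropped,
                 partial_effects = partial_effects(fit, rows,
                                                  setdiff(names(kmap), dropped))),
            class = "squeeze_gam")
}

# Centred partial-effect curves on an evenly spaced 200-point grid per
# smooth.  mgcv's type = "terms" predictions evaluate each smooth at its
# own column only, so a single grid frame serves all terms at once.
partial_effects <- function(fit, rows, vars, n_grid = 200) {
  grid <- as.data.frame(lapply(rows[vars], function(x)
    seq(min(x), max(x), length.out = n_grid)))
  pr <- mgcv::predict.gam(fit, newdata = grid, type = "terms", se.fit = TRUE)
  out <- list()
  for (v in vars) {
    col <- grep(paste0("s\\(", v, "\\)"), colnames(pr$fit))
    if (length(col) != 1) next
    out[[v]] <- data.frame(term = v, grid_value = grid[[v]],
                           effect = pr$fit[, col], se = pr$se.fit[, col])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.squeeze_gam <- function(x, ...) {
  cat(sprintf("squeeze_gam: n = %d, R^2 = %s, residual lag-1 ACF = %.3f\n",
              x$n, formatC(x$r_sq, digits = 3, format = "f"),
              x$resid_acf1))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Long-term trend summary from a fitted squeeze GAM
#'
#' Reports the fractional-year smooth's effective degrees of freedom and
#' p-value, classifies the trend as effectively linear (edf <= 1.1) or
#' nonlinear, and flags significance at \code{alpha}.
#'
#' @param fit a \code{squeeze_gam}.
#' @param alpha significance level for the date smooth.
#' @return list with \code{edf}, \code{p_value}, \code{shape}
#'   ("linear"/"nonlinear"), \code{significant}.
#' @export
long_term_trend_test <- function(fit, alpha = 0.05) {
  row <- fit$terms[fit$terms$term == "date_frac", , drop = FALSE]
  if (nrow(row) == 0) stop("fit has no date term")
  list(edf = row$edf,
       p_value = row$p_value,
       shape = if (row$edf <= 1.1) "linear" else "nonlinear",
       significant = is.finite(row$p_value) && row$p_value < alpha)
}
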