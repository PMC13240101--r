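# Annual regression screen: each winter survey descriptor against each
# prior-summer habitat indicator, with a Bonferroni family-wise correction.

.indicator_cols <- c("min_daily_m3", "min_avg_14d_m3", "min_avg_30d_m3")

#' Pair survey years with prior-year habitat indicators
#'
#' Winter gillnet surveys of year Y respond, if at all, to the squeeze of
#' the previous summer, so survey year Y is paired with indicator year
#' Y - lag.  Years missing either side, or whose indicator year is flagged
#' low-coverage, are dropped.
#'
#' @param survey a \code{survey_table} (columns year, descriptor, value).
#' @param indicators an \code{\link{annual_indicators}} table.
#' @param lag survey-to-indicator year offset (default 1).
#' @param indicator_cols indicator columns to carry (default the pulse and
#'   two press indicators).
#' @param drop_low_coverage drop pairs whose indicator year is flagged.
#' @return long data.frame with one row per (descriptor, survey year,
#'   range, indicator): columns \code{descriptor}, \code{survey_year},
#'   \code{value}, \code{range}, \code{indicator}, \code{habitat_m3}.
#' @export
align_survey_to_indicators <- function(survey, indicators, lag = 1,
                                       indicator_cols = .indicator_cols,
                                       drop_low_coverage = TRUE) {
  ind <- as.data.frame(indicators)
  if (drop_low_coverage && "low_coverage" %in% names(ind))
    ind <- ind[!ind$low_coverage, , drop = FALSE]
  rows <- list(); k <- 1
  for (rg in unique(ind$range)) {
    sub <- ind[ind$range == rg, , drop = FALSE]
    m <- match(survey$year - lag, sub$year)
    for (ic in indicator_cols) {
      hab <- sub[[ic]][m]
      ok <- !is.na(hab) & !is.na(survey$value)
      if (!any(ok)) next
      rows[[k]] <- data.frame(descriptor = survey$descriptor[ok],
                              survey_year = survey$year[ok],
                              value = survey$value[ok],
                              range = rg, indicator = ic,
                              habitat_m3 = hab[ok])
      k <- k + 1
    }
  }
  if (length(rows) == 0)
    stop("no overlap between survey years and indicator years")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (>= 1).
#' @return alpha / m.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1)
    stop("invalid argument: m must be a positive count")
  if (alpha <= 0 || alpha >= 1)
    stop("invalid argument: alpha must lie in (0, 1)")
  alpha / m
}

#' Run the habitat-vs-survey regression screen
#'
#' One ordinary-least-squares regression (single predictor plus intercept,
#' two-sided t-test on the slope) per (range, indicator, descriptor)
#' combination present in the paired table: with the three default squeeze
#' ranges, three indicators, and six descriptors this is the full 54-model
#' family.  Significance is flagged at the Bonferroni-corrected level
#' alpha / m, with m the number of fitted models.
#'
#' @param paired output of \code{\link{align_survey_to_indicators}}.
#' @param alpha family-wise significance level.
#' @return data.frame (class \code{screen_results}) with columns
#'   \code{range}, \code{indicator}, \code{descriptor}, \code{n},
#'   \code{slope}, \code{intercept}, \code{p_value}, \code{degenerate},
#'   \code{significant}; attributes \code{alpha} and \code{alpha_corrected}.
#' @export
run_screen <- function(paired, alpha = 0.05) {
  key <- unique(paired[, c("range", "indicator", "descriptor")])
  rows <- list()
  for (i in seq_len(nrow(key))) {
    sub <- paired[paired$range == key$range[i] &
                  paired$indicator == key$indicator[i] &
                  paired$descriptor == key$descriptor[i], , drop = FALSE]
    n <- nrow(sub)
    if (n < 3)
      stop("regression needs at least 3 year pairs (",
           key$range[i], "/", key$indicator[i], "/", key$descriptor[i],
           " has ", n, ")")
    degen <- stats::sd(sub$habitat_m3) == 0
    if (degen) {
      slope <- NA_real_; intercept <- mean(sub$value); p <- NA_real_
    } else {
      fit <- stats::lm(value ~ habitat_m3, data = sub)
      cf <- summary(fit)$coefficients
      slope <- cf["habitat_m3", "Estimate"]
      intercept <- cf["(Intercept)", "Estimate"]
      p <- cf["habitat_m3", "Pr(>|t|)"]
    }
    rows[[i]] <- data.frame(range = key$range[i], indicator = key$indicator[i],
                            descriptor = key$descriptor[i], n = n,
                            slope = slope, intercept = intercept,
                            p_value = p, degenerate = degen)
  }
  out <- do.call(rbind, rows)
  a_corr <- bonferroni_alpha(alpha, nrow(out))
  out$significant <- !is.na(out$p_value) & out$p_value < a_corr
  rownames(out) <- NULL
  structure(out, class = c("screen_results", "data.frame"),
            alpha = alpha, alpha_corrected = a_corr)
}

#' Summarise a regression screen
#'
#' @param results a \code{screen_results} table.
#' @return list with \code{n_models}, \code{alpha},
#'   \code{alpha_corrected}, \code{min_p}, \code{max_p},
#'   \code{n_significant_corrected}, \code{n_significant_nominal}.
#' @export
screen_summary <- function(results) {
  if (nrow(results) == 0) stop("empty screen results")
  p <- results$p_value[!is.na(results$p_value)]
  alpha <- attr(results, "alpha") %||% 0.05
  a_corr <- attr(results, "alpha_corrected") %||%
    bonferroni_alpha(alpha, nrow(results))
  list(n_models = nrow(results),
       alpha = alpha,
       alpha_corrected = a_corr,
       min_p = if (length(p)) min(p) else NA_real_,
       max_p = if (length(p)) max(p) else NA_real_,
       n_significant_corrected = sum(results$significant, na.rm = TRUE),
       n_significant_nominal = sum(p < alpha))
}

#' @export
print.screen_results <- function(x, ...) {
  s <- screen_summary(x)
  cat(sprintf(
    "screen_results: %d models, alpha %.3g -> corrected %.3g\n", s$n_models,
    s$alpha, s$alpha_corrected))
  cat(sprintf("  p range %.4g .. %.4g; %d significant at corrected alpha\n",
              s$min_p, s$max_p, s$n_significant_corrected))
  invisible(x)
}
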