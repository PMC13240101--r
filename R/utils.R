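# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# One master seed, split per generator so each synthetic component can be
# regenerated independently yet reproducibly.  Kept well below 2^31.
derive_seed <- function(seed, label) {
  offsets <- c(
    bathymetry = 101L, roughness = 157L, levels = 211L,
    profiles = 307L, survey = 401L, pipeline = 503L
  )
  if (!label %in% names(offsets)) stop("unknown seed label: ", label)
  (abs(as.integer(seed)) %% 1000000L) * 1000L + offsets[[label]]
}

#' Canonical day of year
#'
#' Day-of-year index on a 366-day calendar so that a given month-day maps to
#' the same index in every year (Feb 29 is its own day, 60; Mar 1 is always
#' 61).  Keeps multi-year day-of-year grouping aligned across leap and
#' common years.
#' @param dates Date vector.
#' @return integer vector in 1..366.
#' @export
day_of_year366 <- function(dates) {
  md <- format(as.Date(dates), "%m-%d")
  match(md, .leap_md)
}

.leap_md <- format(seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day"),
                   "%m-%d")

#' Fractional-year representation of a date
#'
#' year + day_of_year/365.25, so 1995-01-01 maps to ~1995.003.
#' @param dates Date vector.
#' @return numeric vector.
#' @export
date_fraction <- function(dates) {
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  yr + day_of_year366(dates) / 365.25
}

# Tiny polynomial string hash (hex), used only for run-manifest config hashes.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
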