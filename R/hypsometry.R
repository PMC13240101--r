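# Hypsometry: elevation raster -> area-at-elevation step function by
# discrete cell counting.  Areas are exact integer multiples of the cell
# area; no interpolation anywhere.

#' Bathymetric elevation grid
#'
#' A single-band elevation raster: matrix of metres AMSL (NA = nodata,
#' outside the basin), square cell size, and lower-left origin.
#'
#' @param elevations numeric matrix, m AMSL; NA marks nodata cells.
#' @param cell_size cell edge length in metres (> 0).
#' @param xll,yll coordinates of the lower-left corner (metres).
#' @return object of class \code{bathymetry_grid}.
#' @export
bathymetry_grid <- function(elevations, cell_size, xll = 0, yll = 0) {
  elevations <- as.matrix(elevations)
  storage.mode(elevations) <- "double"
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("invalid grid: cell_size must be positive")
  if (all(is.na(elevations)))
    stop("empty raster: all cells are nodata")
  structure(list(elevations = elevations, cell_size = cell_size,
                 xll = xll, yll = yll),
            class = "bathymetry_grid")
}

#' @export
print.bathymetry_grid <- function(x, ...) {
  d <- dim(x$elevations)
  cat(sprintf("bathymetry_grid: %d x %d cells of %.2f m (%d valid)\n",
              d[1], d[2], x$cell_size, sum(!is.na(x$elevations))))
  rng <- range(x$elevations, na.rm = TRUE)
  cat(sprintf("  elevation range: %.3f .. %.3f m AMSL\n", rng[1], rng[2]))
  invisible(x)
}

#' Write an elevation raster as an ESRI ASCII grid
#'
#' Plain-text raster format carrying ncols/nrows, lower-left origin, square
#' cell size, and a nodata sentinel; values are written row-major from the
#' top row with 17 significant digits so doubles round-trip exactly.
#'
#' @param grid a \code{\link{bathymetry_grid}}.
#' @param path output file path (conventionally \code{.asc}).
#' @param nodata sentinel written for NA cells.
#' @return \code{path}, invisibly.
#' @export
write_elevation_raster <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "bathymetry_grid"))
  m <- grid$elevations
  header <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %s", formatC(grid$xll, digits = 17, format = "g")),
    sprintf("yllcorner %s", formatC(grid$yll, digits = 17, format = "g")),
    sprintf("cellsize %s", formatC(grid$cell_size, digits = 17, format = "g")),
    sprintf("NODATA_value %s", formatC(nodata, digits = 17, format = "g"))
  )
  vals <- m
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an elevation raster from an ESRI ASCII grid
#'
#' Nodata cells are masked to NA; the cell size comes from the header and
#' must be square (a \code{dx}/\code{dy} header with unequal spacing is
#' rejected).
#'
#' @param path file path.
#' @return a \code{\link{bathymetry_grid}}.
#' @export
read_elevation_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows))
    stop("unsupported raster: missing ncols/nrows header")
  cellsize <- hdr$cellsize
  if (is.null(cellsize)) {
    if (is.null(hdr$dx) || is.null(hdr$dy))
      stop("unsupported raster: no cellsize (or dx/dy) in header")
    if (abs(hdr$dx - hdr$dy) > 1e-6 * max(abs(hdr$dx), abs(hdr$dy)))
      stop("unsupported raster: non-square cells (dx != dy)")
    cellsize <- hdr$dx
  }
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("unsupported raster: expected ", nr * nc, " values, got ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  if (all(is.na(m))) stop("empty raster: all cells are nodata")
  bathymetry_grid(m, cell_size = cellsize,
                  xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0)
}

#' Compose bathymetry with a DEM into one continuous elevation surface
#'
#' Reservoir bathymetry typically stops at the top of the conservation
#' pool; the surrounding DEM supplies elevations above it (the flood pool).
#' The composite takes the bathymetric elevation wherever it is valid and
#' the DEM elevation elsewhere, yielding a raster that covers every water
#' level the lake can reach.
#'
#' @param bathy,dem aligned \code{\link{bathymetry_grid}}s (same dimensions,
#'   cell size, and origin).
#' @return a \code{\link{bathymetry_grid}}.
#' @export
combine_bathymetry_dem <- function(bathy, dem) {
  stopifnot(inherits(bathy, "bathymetry_grid"), inherits(dem, "bathymetry_grid"))
  if (!identical(dim(bathy$elevations), dim(dem$elevations)) ||
      abs(bathy$cell_size - dem$cell_size) > 1e-9 * bathy$cell_size ||
      bathy$xll != dem$xll || bathy$yll != dem$yll)
    stop("alignment error: grids differ in shape, cell size, or origin")
  out <- bathy$elevations
  use_dem <- is.na(out)
  out[use_dem] <- dem$elevations[use_dem]
  bathymetry_grid(out, cell_size = bathy$cell_size,
                  xll = bathy$xll, yll = bathy$yll)
}

#' Build the hypsometric area-at-elevation curve
#'
#' For any elevation z the submerged area is (number of valid cells with
#' elevation <= z) times the cell area -- an exact right-continuous step
#' function stored as sorted unique elevations with cumulative cell counts.
#'
#' @param grid a \code{\link{bathymetry_grid}}.
#' @return object of class \code{hypsometric_curve} with fields
#'   \code{elevations}, \code{cum_cells}, \code{cell_area}.
#' @export
build_hypsometric_curve <- function(grid) {
  stopifnot(inherits(grid, "bathymetry_grid"))
  v <- grid$elevations[!is.na(grid$elevations)]
  elev <- sort(unique(v))
  counts <- cumsum(tabulate(match(sort(v), elev), nbins = length(elev)))
  structure(list(elevations = elev, cum_cells = counts,
                 cell_area = grid$cell_size^2),
            class = "hypsometric_curve")
}

#' @export
print.hypsometric_curve <- function(x, ...) {
  cat(sprintf("hypsometric_curve: %d steps over %.3f .. %.3f m AMSL\n",
              length(x$elevations), min(x$elevations), max(x$elevations)))
  cat(sprintf("  cell area %.2f m^2, full-pool area %.4g m^2\n",
              x$cell_area, max(x$cum_cells) * x$cell_area))
  invisible(x)
}

#' Submerged surface area at a water-plane elevation
#'
#' Exact step-function evaluation: cells at exactly z count as submerged.
#' Vectorised over \code{z}; non-decreasing in z.
#'
#' @param curve a \code{\link{hypsometric_curve}}.
#' @param z elevation(s), m AMSL; must be finite.
#' @return area(s) in m^2.
#' @export
area_at_elevation <- function(curve, z) {
  stopifnot(inherits(curve, "hypsometric_curve"))
  if (any(!is.finite(z)))
    stop("invalid argument: z must be finite")
  idx <- findInterval(z, curve$elevations)
  counts <- c(0, curve$cum_cells)[idx + 1]
  counts * curve$cell_area
}

#' Export a hypsometric curve as a data frame
#'
#' @param x a \code{\link{hypsometric_curve}}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns \code{elevation_m},
#'   \code{cumulative_area_m2}.
#' @export
as.data.frame.hypsometric_curve <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(elevation_m = x$elevations,
             cumulative_area_m2 = x$cum_cells * x$cell_area)
}
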