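# Lightweight single-band raster container and plain-text (ESRI ASCII grid)
# I/O, plus Horn slope/aspect. Matrices are stored with row 1 = northernmost
# row, matching the on-disk row order of the ASCII grid format.

#' Construct a single-band raster grid
#'
#' @param values Numeric matrix; row 1 is the northern edge.
#' @param cellsize Cell size in metres.
#' @param xll,yll Coordinates of the lower-left corner (map units).
#' @param nodata Value used for missing cells on disk.
#' @return An object of class `terp_raster`.
#' @export
terp_raster <- function(values, cellsize = 30, xll = 0, yll = 0,
                        nodata = -9999) {
  stopifnot(is.matrix(values))
  structure(list(values = values, cellsize = cellsize, xll = xll, yll = yll,
                 nodata = nodata),
            class = "terp_raster")
}

#' @export
print.terp_raster <- function(x, ...) {
  cat(sprintf("terp_raster: %d x %d cells, cellsize %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @return A [terp_raster()].
#' @export
read_ascii_grid <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, n = 1)), "\\s+")[[1]]
    hdr[[tolower(ln[1])]] <- as.numeric(ln[2])
  }
  vals <- scan(con, what = numeric(), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  terp_raster(m, cellsize = hdr$cellsize, xll = hdr$xllcorner,
              yll = hdr$yllcorner, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param r A [terp_raster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  m <- r$values
  m[is.na(m)] <- r$nodata
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", r$xll),
           sprintf("yllcorner %.10g", r$yll),
           sprintf("cellsize %.10g", r$cellsize),
           sprintf("NODATA_value %.10g", r$nodata))
  body <- apply(m, 1, function(row) paste(format(row, trim = TRUE,
                                                 digits = 10),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# shift a matrix by (dr, dc) with edge replication
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1), nc)
  m[ri, ci, drop = FALSE]
}

#' Slope and aspect from a DEM (Horn's method)
#'
#' Computes per-cell slope and downslope aspect on the 3x3 neighbourhood
#' with edge replication. Aspect is measured clockwise from north and is the
#' direction the surface faces (direction of steepest descent).
#'
#' @param dem A [terp_raster()] of elevations (m).
#' @return List with `slope` and `aspect` matrices (radians).
#' @export
horn_slope_aspect <- function(dem) {
  z <- dem$values
  cs <- dem$cellsize
  z1 <- shift_mat(z, -1, -1); z2 <- shift_mat(z, -1, 0); z3 <- shift_mat(z, -1, 1)
  z4 <- shift_mat(z,  0, -1);                             z6 <- shift_mat(z,  0, 1)
  z7 <- shift_mat(z,  1, -1); z8 <- shift_mat(z,  1, 0); z9 <- shift_mat(z,  1, 1)
  # row 1 is north, so "up" rows (z1..z3) have larger y
  dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * cs)
  dzdy <- ((z1 + 2 * z2 + z3) - (z7 + 2 * z8 + z9)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2))
  aspect <- atan2(-dzdx, -dzdy) %% (2 * pi)
  list(slope = slope, aspect = aspect)
}

#' Build a terrain model from a DEM
#'
#' Bundles the elevation raster with derived slope/aspect and the site
#' geographic position used for solar geometry.
#'
#' @param dem A [terp_raster()] of elevations (m).
#' @param lat,lon Site latitude/longitude in degrees.
#' @param utc_offset Local-time offset from UTC in hours (default KST, +9).
#' @return An object of class `terrain_model`.
#' @export
terrain_model <- function(dem, lat, lon, utc_offset = 9) {
  if (abs(lat) > 90) stop("latitude out of range")
  sa <- horn_slope_aspect(dem)
  structure(list(dem = dem, slope = sa$slope, aspect = sa$aspect,
                 lat = lat, lon = lon, utc_offset = utc_offset),
            class = "terrain_model")
}
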