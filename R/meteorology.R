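# Driver preparation: PPFD from pyranometer radiation, trailing 24 h/240 h
# means, solar ephemeris, and the per-pixel topographic incidence factor.

MJ_PER_H_TO_W <- 277.78   # MJ m-2 h-1 -> W m-2
W_TO_PPFD <- 2.02         # umol J-1, shortwave -> photon flux

#' Convert hourly solar radiation to PPFD
#'
#' Applies the factor 277.78 (MJ m-2 h-1 to W m-2) followed by
#' 2.02 umol W-1 s-1.
#'
#' @param radiation Hourly solar radiation, MJ m-2 h-1.
#' @return PPFD in umol m-2 s-1.
#' @export
solar_to_ppfd <- function(radiation) {
  if (any(radiation < 0, na.rm = TRUE)) stop("radiation must be non-negative")
  radiation * MJ_PER_H_TO_W * W_TO_PPFD
}

# Trailing mean over the previous n samples (inclusive of the current one);
# while fewer than n samples of history exist the mean expands over all
# available history.
trailing_mean <- function(x, n) {
  cs <- cumsum(x)
  idx <- seq_along(x)
  lag <- idx - n
  prev <- ifelse(lag >= 1, cs[pmax(lag, 1)], 0)
  (cs - prev) / pmin(idx, n)
}

#' Fill rolling 24 h / 240 h driver means
#'
#' Adds trailing-mean temperature and PPFD columns (`t24`, `t240`, `p24`,
#' `p240`) to an hourly met table. The first 240 hours of a run use an
#' expanding mean over the available history and are flagged as warm-up.
#'
#' @param met Data frame with columns `timestamp` (hourly `POSIXct`),
#'   `temp_k`, `ppfd`.
#' @return `met` with the four rolling columns and a logical `warmup` column.
#' @export
rolling_drivers <- function(met) {
  stopifnot(all(c("timestamp", "temp_k", "ppfd") %in% names(met)))
  if (nrow(met) > 1) {
    dt <- as.numeric(difftime(met$timestamp[-1],
                              met$timestamp[-nrow(met)], units = "hours"))
    if (any(abs(dt - 1) > 1e-6)) {
      stop("met series must be hourly and gap-free")
    }
  }
  met$t24 <- trailing_mean(met$temp_k, 24)
  met$t240 <- trailing_mean(met$temp_k, 240)
  met$p24 <- trailing_mean(met$ppfd, 24)
  met$p240 <- trailing_mean(met$ppfd, 240)
  met$warmup <- seq_len(nrow(met)) < 240
  met
}

#' Solar position (zenith and azimuth)
#'
#' Standard low-precision ephemeris (Spencer fractional-year expansions of
#' declination and the equation of time), accurate to a fraction of a degree
#' -- ample for the topographic incidence cosine.
#'
#' @param lat,lon Degrees (positive north / east).
#' @param timestamp `POSIXct` in local standard time.
#' @param utc_offset Hours ahead of UTC of the local clock (KST = +9).
#' @return List with `zenith` and `azimuth` in radians; azimuth is clockwise
#'   from north.
#' @export
solar_position <- function(lat, lon, timestamp, utc_offset = 9) {
  if (abs(lat) > 90) stop("latitude out of range")
  lt <- as.POSIXlt(timestamp)
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  tst <- hour * 60 + eqtime + 4 * lon - 60 * utc_offset
  ha <- (tst / 4 - 180) * pi / 180   # hour angle, 0 at solar noon
  phi <- lat * pi / 180
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  cosz <- pmin(pmax(cosz, -1), 1)
  zenith <- acos(cosz)
  # azimuth from south (west positive), then rotate to clockwise-from-north
  az_s <- atan2(sin(ha), cos(ha) * sin(phi) - tan(decl) * cos(phi))
  azimuth <- (az_s + pi) %% (2 * pi)
  list(zenith = zenith, azimuth = azimuth)
}

#' Topographic solar-incidence factor
#'
#' Ratio of direct-beam irradiance on a tilted surface to that on a
#' horizontal surface: the cosine of the sun/surface-normal angle divided by
#' the cosine of the solar zenith. Zero when the sun is below the horizon or
#' behind the slope; the ratio is capped to avoid the low-sun blow-up of the
#' cos-zenith denominator (measured horizontal radiation is near zero there
#' anyway).
#'
#' @param slope,aspect Surface slope and downslope aspect (radians, aspect
#'   clockwise from north).
#' @param zenith,azimuth Solar position (radians).
#' @param cap Upper bound on the ratio (default 3).
#' @param floor_eps Lower floor on the cos-zenith denominator.
#' @return Dimensionless factor in `[0, cap]`.
#' @export
incidence_factor <- function(slope, aspect, zenith, azimuth,
                             cap = 3, floor_eps = 1e-3) {
  cosi <- cos(slope) * cos(zenith) +
    sin(slope) * sin(zenith) * cos(azimuth - aspect)
  f <- pmax(cosi, 0) / pmax(cos(zenith), floor_eps)
  f <- pmin(f, cap)
  f[zenith >= pi / 2] <- 0
  f
}

#' Apply the topographic correction to a PPFD series over a terrain grid
#'
#' Multiplies the horizontal-surface PPFD by the per-pixel incidence factor
#' for every hour, then recomputes the rolling 24 h/240 h PPFD history from
#' the corrected per-pixel series.
#'
#' @param met Hourly met table (see [rolling_drivers()]).
#' @param terrain A [terrain_model()].
#' @param cap,floor_eps Passed to [incidence_factor()].
#' @return List with matrices (`pixels x hours`) `ppfd`, `p24`, `p240`, the
#'   incidence `factor`, and the hour timestamps. Pixels are in column-major
#'   raster order.
#' @export
apply_topographic_ppfd <- function(met, terrain, cap = 3, floor_eps = 1e-3) {
  sp <- solar_position(terrain$lat, terrain$lon, met$timestamp,
                       terrain$utc_offset)
  slope <- as.vector(terrain$slope)
  aspect <- as.vector(terrain$aspect)
  fac <- incidence_matrix(slope, aspect, sp$zenith, sp$azimuth,
                          cap = cap, floor_eps = floor_eps)
  ppfd <- fac * rep(met$ppfd, each = length(slope))
  list(timestamp = met$timestamp,
       factor = fac,
       ppfd = ppfd,
       p24 = t(apply(ppfd, 1, trailing_mean, n = 24)),
       p240 = t(apply(ppfd, 1, trailing_mean, n = 240)))
}

# incidence factors for all (pixel, hour) pairs via outer products
incidence_matrix <- function(slope, aspect, zenith, azimuth,
                             cap = 3, floor_eps = 1e-3) {
  cosi <- outer(cos(slope), cos(zenith)) +
    outer(sin(slope) * cos(aspect), sin(zenith) * cos(azimuth)) +
    outer(sin(slope) * sin(aspect), sin(zenith) * sin(azimuth))
  denom <- pmax(cos(zenith), floor_eps)
  f <- pmax(cosi, 0) / rep(denom, each = length(slope))
  f <- pmin(f, cap)
  f[, zenith >= pi / 2] <- 0
  f
}

#' Read an hourly weather CSV
#'
#' Expects columns `timestamp`, `temperature`, `solar_radiation`
#' (MJ m-2 h-1). Temperature unit is declared, not guessed.
#'
#' @param path CSV path.
#' @param temp_unit `"K"` or `"C"`.
#' @param tz Time zone of the timestamps (default `"UTC"` used as a fixed
#'   local-standard-time label; solar geometry uses the explicit UTC offset).
#' @return Data frame with `timestamp`, `temp_k`, `ppfd`.
#' @export
read_weather_csv <- function(path, temp_unit = c("K", "C"), tz = "UTC") {
  temp_unit <- match.arg(temp_unit)
  w <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "temperature", "solar_radiation") %in% names(w)))
  out <- data.frame(
    timestamp = as.POSIXct(w$timestamp, tz = tz),
    temp_k = if (temp_unit == "C") w$temperature + 273.15 else w$temperature,
    ppfd = solar_to_ppfd(w$solar_radiation)
  )
  out
}
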