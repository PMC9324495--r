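# Shared fixtures: standard-condition drivers, tiny scenarios, and an
# hourly weather stub.

std_met <- function() {
  std <- standard_conditions()
  list(t = std$t_inst, ppfd = std$p_inst, t24 = std$t_avg, t240 = std$t_avg,
       p24 = std$p_avg_sun, p240 = std$p_avg_sun)
}

# constant standard-condition weather covering `hours` hours
std_weather <- function(hours = 24, year = 2020) {
  std <- standard_conditions()
  ts <- seq(as.POSIXct(sprintf("%d-06-01 00:00:00", year), tz = "UTC"),
            by = "hour", length.out = hours)
  data.frame(timestamp = ts, temp_k = std$t_inst, ppfd = std$p_inst)
}

# flat single-pixel terrain
flat_terrain_1px <- function() {
  dem <- terp_raster(matrix(100, 3, 3), cellsize = 30)
  tr <- terrain_model(dem, lat = 37.5, lon = 127.5)
  # keep only the centre pixel view by construction: a 1x1 grid of slope 0
  tr$slope <- matrix(0, 1, 1)
  tr$aspect <- matrix(0, 1, 1)
  tr$dem <- terp_raster(matrix(100, 1, 1), cellsize = 30)
  tr
}

small_scenario <- function(seed = 7, nrow = 10, ncol = 10) {
  synthetic_scenario(seed = seed, nrow = nrow, ncol = ncol)
}

# constant-LAI stack over the full year for n pixels
const_lai <- function(npix, lai = 5, days = 1:366) {
  lai_stack(days, matrix(lai, npix, length(days)))
}
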