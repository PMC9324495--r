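# Seeded synthetic inputs with the statistical structure the analysis
# assumes: a temperate annual + diurnal temperature cycle, clear-sky
# radiation damped by cloud (strongly so in a mid-summer monsoon window),
# a hilly DEM, a contiguous PFT mosaic, and NDVI with a double-logistic
# deciduous seasonal course, noise and monsoon-depressed outliers.
# Every generator is a pure function of (scenario, seed): the global RNG
# state is saved and restored around each draw.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Define a synthetic study scenario
#'
#' Bundles every knob of the synthetic landscape and year. Defaults emulate
#' a temperate Korean basin: latitude 37.5 N, a 50x50 grid of 30 m cells,
#' an East Asian monsoon window around days 172-225, and a forest mosaic of
#' 61.7% deciduous, 31.0% conifer and 6.4% mixed stands.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param year Simulation year.
#' @param nrow,ncol,cellsize Grid shape and cell size (m).
#' @param lat,lon,utc_offset Site position and clock offset.
#' @param monsoon Day-of-year window of the summer rainy season.
#' @param temp Temperature model: annual mean (K), annual and diurnal
#'   amplitudes (K), AR(1) noise sd and coefficient.
#' @param radiation Clear-sky peak irradiance (W m-2) and mean/sd of the
#'   daily cloud transmission factor inside and outside the monsoon.
#' @param ndvi Per-PFT truth parameters, observation cadence (days), noise
#'   sd, and the outlier process (rates in/out of the monsoon window and
#'   the downward depth range).
#' @param pft_targets Forest composition targets (fractions of forest).
#' @param forest_fraction Fraction of the grid that is forest.
#' @param dem Base elevation (m), number of Gaussian hills, amplitude and
#'   width ranges (m).
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 42, year = 2020, nrow = 50, ncol = 50,
                               cellsize = 30, lat = 37.5, lon = 127.5,
                               utc_offset = 9, monsoon = c(172, 225),
                               temp = list(mean = 284.5, annual_amp = 12,
                                           diurnal_amp = 4, sigma = 1.2,
                                           phi = 0.8),
                               radiation = list(clear_sky = 1000,
                                                cloud_mean = 0.72,
                                                cloud_monsoon = 0.42,
                                                cloud_sd = 0.15),
                               ndvi = list(cadence_days = 5, sigma = 0.03,
                                           dec_mn = 0.32, dec_mx = 0.85,
                                           dec_sos = 115, dec_rsp = 0.09,
                                           dec_eos = 290, dec_rsw = 0.07,
                                           con_level = 0.72, con_amp = 0.05,
                                           outlier_rate_monsoon = 0.15,
                                           outlier_rate = 0.033,
                                           outlier_depth = c(0.3, 0.7)),
                               pft_targets = c(broadleaf_deciduous = 0.617,
                                               needleleaf_conifer = 0.310,
                                               mixed = 0.064),
                               forest_fraction = 0.936,
                               dem = list(base = 250, n_hills = 6,
                                          amp = c(150, 450),
                                          width = c(200, 800))) {
  if (sum(pft_targets) > 1 + 1e-9) stop("PFT composition targets exceed 1")
  if (temp$sigma < 0 || ndvi$sigma < 0) stop("noise sd must be non-negative")
  structure(list(seed = seed, year = year, nrow = nrow, ncol = ncol,
                 cellsize = cellsize, lat = lat, lon = lon,
                 utc_offset = utc_offset, monsoon = monsoon, temp = temp,
                 radiation = radiation, ndvi = ndvi,
                 pft_targets = pft_targets,
                 forest_fraction = forest_fraction, dem = dem),
            class = "synthetic_scenario")
}

#' Generate an hourly synthetic weather year
#'
#' Temperature is an annual sinusoid (peak in early August) plus a diurnal
#' sinusoid (peak mid-afternoon) plus AR(1) noise. Radiation is the
#' clear-sky geometric curve at the site latitude damped by a daily cloud
#' transmission factor whose mean drops inside the monsoon window.
#'
#' @param scenario A [synthetic_scenario()].
#' @return Data frame with `timestamp`, `temp_k`, `solar_mj` (MJ m-2 h-1)
#'   and `ppfd`.
#' @export
gen_weather <- function(scenario) {
  with_seed(scenario$seed + 1L, {
    t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", scenario$year), tz = "UTC")
    t1 <- as.POSIXct(sprintf("%d-12-31 23:00:00", scenario$year), tz = "UTC")
    ts <- seq(t0, t1, by = "hour")
    lt <- as.POSIXlt(ts)
    doy <- lt$yday + 1
    hr <- lt$hour
    nt <- length(ts)
    tm <- scenario$temp
    # annual peak around day 217 (early August), diurnal peak at 15:00
    base <- tm$mean + tm$annual_amp * cos(2 * pi * (doy - 217) / 365.25) +
      tm$diurnal_amp * cos(2 * pi * (hr - 15) / 24)
    noise <- numeric(nt)
    eps <- rnorm(nt, 0, tm$sigma * sqrt(1 - tm$phi^2))
    noise[1] <- rnorm(1, 0, tm$sigma)
    for (i in 2:nt) noise[i] <- tm$phi * noise[i - 1] + eps[i]
    temp_k <- base + noise

    sp <- solar_position(scenario$lat, scenario$lon, ts, scenario$utc_offset)
    pot_w <- scenario$radiation$clear_sky * pmax(cos(sp$zenith), 0)
    ndays <- max(doy)
    day_mean <- ifelse(seq_len(ndays) >= scenario$monsoon[1] &
                         seq_len(ndays) <= scenario$monsoon[2],
                       scenario$radiation$cloud_monsoon,
                       scenario$radiation$cloud_mean)
    cloud_day <- pmin(pmax(rnorm(ndays, day_mean, scenario$radiation$cloud_sd),
                           0.1), 1)
    solar_w <- pot_w * cloud_day[doy]
    solar_mj <- solar_w * 3600 / 1e6
    data.frame(timestamp = ts, temp_k = temp_k, solar_mj = solar_mj,
               ppfd = solar_to_ppfd(solar_mj))
  })
}

#' Generate a synthetic hilly DEM
#'
#' Sum of randomly placed Gaussian hills on a base elevation; steep enough
#' that all four aspect classes are well represented.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [terrain_model()].
#' @export
gen_terrain <- function(scenario) {
  with_seed(scenario$seed + 2L, {
    nr <- scenario$nrow; nc <- scenario$ncol; cs <- scenario$cellsize
    x <- (col(matrix(0, nr, nc)) - 0.5) * cs
    y <- (nr - row(matrix(0, nr, nc)) + 0.5) * cs
    z <- matrix(scenario$dem$base, nr, nc)
    for (k in seq_len(scenario$dem$n_hills)) {
      cx <- runif(1, 0, nc * cs); cy <- runif(1, 0, nr * cs)
      amp <- runif(1, scenario$dem$amp[1], scenario$dem$amp[2])
      w <- runif(1, scenario$dem$width[1], scenario$dem$width[2])
      z <- z + amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * w^2))
    }
    dem <- terp_raster(z, cellsize = cs)
    terrain_model(dem, lat = scenario$lat, lon = scenario$lon,
                  utc_offset = scenario$utc_offset)
  })
}

#' Generate a contiguous PFT mosaic
#'
#' The lowest-elevation fraction of the grid becomes non-forest (valley
#' agricultural land); the remaining forest pixels are partitioned into
#' contiguous deciduous / conifer / mixed patches by seeded multi-source
#' region growth with class quotas matching the composition targets.
#'
#' @param scenario A [synthetic_scenario()].
#' @param terrain Terrain from [gen_terrain()].
#' @return Character matrix of PFT codes (see [pft_cover()]).
#' @export
gen_pft <- function(scenario, terrain) {
  with_seed(scenario$seed + 3L, {
    nr <- scenario$nrow; nc <- scenario$ncol
    npix <- nr * nc
    elev <- as.vector(terrain$dem$values)
    n_nonforest <- round(npix * (1 - scenario$forest_fraction))
    assign_ <- rep(NA_character_, npix)
    if (n_nonforest > 0) {
      assign_[order(elev)[seq_len(n_nonforest)]] <- "nonforest"
    }
    forest_idx <- which(is.na(assign_))
    quota <- round(scenario$pft_targets * length(forest_idx))
    quota[1] <- length(forest_idx) - sum(quota[-1])
    classes <- names(quota)
    n_seeds <- pmax(round(quota / 120), 1)
    frontier <- list()
    placed <- setNames(numeric(length(classes)), classes)
    for (cl in classes) {
      sd_ <- sample(forest_idx[is.na(assign_[forest_idx])], n_seeds[cl])
      assign_[sd_] <- cl
      placed[cl] <- length(sd_)
      frontier[[cl]] <- sd_
    }
    nbr <- function(i) {
      r <- (i - 1) %% nr + 1; c_ <- (i - 1) %/% nr + 1
      out <- c(if (r > 1) i - 1, if (r < nr) i + 1,
               if (c_ > 1) i - nr, if (c_ < nc) i + nr)
      out
    }
    while (any(placed < quota)) {
      open <- classes[placed < quota & vapply(frontier, length, 1L)[classes] > 0]
      if (length(open) == 0) {
        # teleport: drop a fresh seed for a deficient class
        defic <- classes[placed < quota]
        free <- which(is.na(assign_))
        if (length(free) == 0) break
        cl <- defic[1]
        sd_ <- free[sample.int(length(free), 1)]
        assign_[sd_] <- cl
        placed[cl] <- placed[cl] + 1
        frontier[[cl]] <- sd_
        next
      }
      cl <- if (length(open) == 1) open else sample(open, 1, prob = (quota - placed)[open])
      f <- frontier[[cl]]
      i <- f[sample.int(length(f), 1)]
      cand <- nbr(i)
      cand <- cand[is.na(assign_[cand])]
      if (length(cand) == 0) {
        frontier[[cl]] <- setdiff(f, i)
      } else {
        j <- if (length(cand) == 1) cand else sample(cand, 1)
        assign_[j] <- cl
        placed[cl] <- placed[cl] + 1
        frontier[[cl]] <- c(f, j)
      }
    }
    assign_[is.na(assign_)] <- classes[1]
    matrix(assign_, nr, nc)
  })
}

#' Generate a synthetic NDVI observation stack
#'
#' Per-pixel truth: deciduous pixels follow a double-logistic seasonal
#' course (with small per-pixel parameter jitter), conifer pixels a high
#' plateau with mild seasonality, mixed pixels the average of the two, and
#' non-forest a low seasonal curve. Gaussian observation noise is added,
#' plus downward outliers (cloud/monsoon contamination) concentrated in the
#' monsoon window. Truth curves and injected outlier positions are
#' returned for recovery tests.
#'
#' @param scenario A [synthetic_scenario()].
#' @param pft PFT matrix from [gen_pft()].
#' @return List with `doy` (observation days), `values`
#'   (`pixels x dates` NDVI), `truth` (noise-free NDVI matrix),
#'   `truth_params` (per-pixel deciduous curve parameters or `NA`), and
#'   `outliers` (logical injection mask).
#' @export
gen_ndvi <- function(scenario, pft) {
  with_seed(scenario$seed + 4L, {
    p <- as.vector(pft)
    npix <- length(p)
    nv <- scenario$ndvi
    doy <- seq(3, 363, by = nv$cadence_days)
    nob <- length(doy)
    truth <- matrix(NA_real_, npix, nob)
    params <- data.frame(mn = rep(NA_real_, npix), mx = NA_real_,
                         sos = NA_real_, rsp = NA_real_, eos = NA_real_,
                         rsw = NA_real_)
    dec_curve <- function(i) {
      mn <- nv$dec_mn + rnorm(1, 0, 0.015)
      mx <- nv$dec_mx + rnorm(1, 0, 0.015)
      sos <- nv$dec_sos + rnorm(1, 0, 4)
      eos <- nv$dec_eos + rnorm(1, 0, 4)
      params[i, ] <<- c(mn, mx, sos, nv$dec_rsp, eos, nv$dec_rsw)
      double_logistic(doy, mn, mx, sos, nv$dec_rsp, eos, nv$dec_rsw)
    }
    con_curve <- function() {
      nv$con_level - nv$con_amp * cos(2 * pi * (doy - 217) / 365.25)
    }
    for (i in seq_len(npix)) {
      truth[i, ] <- switch(p[i],
        broadleaf_deciduous = dec_curve(i),
        needleleaf_conifer = con_curve(),
        mixed = (dec_curve(i) + con_curve()) / 2,
        nonforest = 0.22 + 0.08 * sin(2 * pi * (doy - 120) / 365)
      )
    }
    vals <- truth + matrix(rnorm(npix * nob, 0, nv$sigma), npix, nob)
    in_monsoon <- doy >= scenario$monsoon[1] & doy <= scenario$monsoon[2]
    rate <- ifelse(in_monsoon, nv$outlier_rate_monsoon, nv$outlier_rate)
    out_mask <- matrix(runif(npix * nob), npix, nob) <
      matrix(rate, npix, nob, byrow = TRUE)
    depth <- matrix(runif(npix * nob, nv$outlier_depth[1],
                          nv$outlier_depth[2]), npix, nob)
    vals[out_mask] <- vals[out_mask] - depth[out_mask]
    vals <- pmin(pmax(vals, -1), 1)
    list(doy = doy, values = vals, truth = truth, truth_params = params,
         outliers = out_mask)
  })
}

#' Generate a complete synthetic scenario bundle
#'
#' Convenience wrapper running all four generators.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `weather`, `terrain`, `pft`, `ndvi`.
#' @export
gen_scenario_data <- function(scenario = synthetic_scenario()) {
  terrain <- gen_terrain(scenario)
  pft <- gen_pft(scenario, terrain)
  list(weather = gen_weather(scenario), terrain = terrain, pft = pft,
       ndvi = gen_ndvi(scenario, pft))
}
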