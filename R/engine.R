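# Per-pixel, per-hour, per-compound emission simulation over a PFT mosaic:
# F_i = gamma_i * sum_j epsilon_{i,j} chi_j, evaluated hourly over the grid
# with the topographic PPFD correction and piecewise-constant daily LAI and
# leaf-age fractions. Pixels are processed in chunks to bound memory; the
# chunk size has no effect on values.

#' Per-pixel cover fractions from a PFT raster
#'
#' Needleleaf-conifer pixels carry cover (1, 0), broadleaf-deciduous (0, 1),
#' mixed forest (0.5, 0.5) -- mixed stands hold conifer and deciduous trees
#' at roughly equal levels -- and non-forest (0, 0).
#'
#' @param pft Character vector/matrix with values among
#'   `"needleleaf_conifer"`, `"broadleaf_deciduous"`, `"mixed"`,
#'   `"nonforest"`.
#' @return List with numeric vectors `chi_conifer`, `chi_deciduous` and the
#'   logical `forest` mask.
#' @export
pft_cover <- function(pft) {
  p <- as.vector(pft)
  bad <- setdiff(unique(p), PFT_LEVELS)
  if (length(bad) > 0) stop("unknown PFT code(s): ", paste(bad, collapse = ", "))
  chi_c <- (p == "needleleaf_conifer") + 0.5 * (p == "mixed")
  chi_d <- (p == "broadleaf_deciduous") + 0.5 * (p == "mixed")
  list(chi_conifer = chi_c, chi_deciduous = chi_d, forest = p != "nonforest")
}

#' Emission flux of one pixel from per-compound activity factors
#'
#' `F_i = gamma_i (epsilon_conifer,i chi_conifer +
#'         epsilon_deciduous,i chi_deciduous)`.
#'
#' @param gamma Named vector of total activity factors per compound.
#' @param cover Numeric vector `c(conifer, deciduous)` cover fractions.
#' @param table Emission-rate table ([load_emission_table()]).
#' @param compounds Compound names; defaults to `names(gamma)`.
#' @return Named vector of fluxes (ug m-2 h-1).
#' @export
pixel_emission <- function(gamma, cover, table, compounds = names(gamma)) {
  if (any(cover < 0) || sum(cover) > 1 + 1e-9) stop("invalid cover fractions")
  if (any(gamma < 0, na.rm = TRUE)) stop("activity factors must be >= 0")
  vapply(compounds, function(cp) {
    g <- gamma[[cp]]
    g * (epsilon(table, cp, "needleleaf_conifer") * cover[1] +
           epsilon(table, cp, "broadleaf_deciduous") * cover[2])
  }, numeric(1))
}

# vectorised leaf-age fractions over pixels (one interval, scalar t_t)
leaf_age_fractions_vec <- function(lai_c, lai_p, t_days, t_t) {
  n <- length(lai_c)
  f <- matrix(0, n, 4, dimnames = list(NULL, c("f_new", "f_gro", "f_mat", "f_sen")))
  eq <- lai_c == lai_p
  dec <- lai_c < lai_p
  gro <- lai_c > lai_p
  if (any(eq)) {
    f[eq, ] <- matrix(c(0, 0.1, 0.8, 0.1), sum(eq), 4, byrow = TRUE)
  }
  if (any(dec)) {
    f[dec, "f_mat"] <- lai_c[dec] / lai_p[dec]
    f[dec, "f_sen"] <- (lai_p[dec] - lai_c[dec]) / lai_p[dec]
  }
  if (any(gro)) {
    ti <- bud_break_ti(t_t)
    tm <- 2.3 * ti
    r <- lai_p[gro] / lai_c[gro]
    fn <- if (t_days <= ti) 1 - r else (ti / t_days) * (1 - r)
    fm <- if (t_days <= tm) r else r + ((t_days - tm) / t_days) * (1 - r)
    f[gro, "f_new"] <- fn
    f[gro, "f_mat"] <- fm
    f[gro, "f_gro"] <- pmax(1 - fn - fm, 0)
  }
  f
}

#' Daily LAI stack for a grid
#'
#' @param days Integer day-of-year of each column.
#' @param values `pixels x days` matrix of LAI (pixels in column-major
#'   raster order).
#' @return Object of class `lai_stack`.
#' @export
lai_stack <- function(days, values) {
  stopifnot(ncol(values) == length(days), all(values >= 0, na.rm = TRUE))
  structure(list(days = as.integer(days), values = values),
            class = "lai_stack")
}

#' Smooth a gridded NDVI stack into a daily LAI stack
#'
#' Runs the per-pixel phenology chain ([smooth_lai()]) over every forest
#' pixel: Hampel repair, NDVI-to-LAI conversion and double-logistic
#' smoothing. Non-forest pixels get zero LAI.
#'
#' @param doy Day-of-year of the NDVI observations.
#' @param ndvi `pixels x observations` NDVI matrix.
#' @param pft PFT codes per pixel (see [pft_cover()]); `NULL` treats all
#'   pixels as forest.
#' @param days Evaluation days (default 1..365).
#' @param window,nsigma Hampel parameters.
#' @return List with the [lai_stack()], per-pixel `method` (fit or linear
#'   fallback), and the `outliers` mask matrix.
#' @export
smooth_lai_grid <- function(doy, ndvi, pft = NULL, days = 1:365,
                            window = 3, nsigma = 3) {
  npix <- nrow(ndvi)
  forest <- if (is.null(pft)) rep(TRUE, npix) else pft_cover(pft)$forest
  vals <- matrix(0, npix, length(days))
  method <- rep(NA_character_, npix)
  outliers <- matrix(FALSE, npix, ncol(ndvi))
  for (i in seq_len(npix)) {
    if (!forest[i]) next
    sm <- smooth_lai(doy, ndvi[i, ], days = days, window = window,
                     nsigma = nsigma)
    vals[i, ] <- sm$fitted
    method[i] <- sm$method
    outliers[i, ] <- sm$outliers
  }
  list(lai = lai_stack(days, vals), method = method, outliers = outliers)
}

#' Run the emission model over a grid
#'
#' Hourly simulation of per-pixel, per-compound emission fluxes for the
#' period covered by the weather table. Temperature is spatially uniform;
#' PPFD is corrected per pixel by the topographic incidence factor, and the
#' 24 h/240 h light history is computed from the corrected series. Daily
#' LAI and the leaf-age fractions (fixed-interval steps) are held
#' piecewise-constant. Deciduous (and the deciduous half of mixed) canopies
#' use the phenological leaf-age factor; conifer canopies use 1.
#'
#' @param weather Hourly data frame with `timestamp`, `temp_k`, `ppfd`.
#' @param terrain A [terrain_model()].
#' @param pft Character matrix/vector of PFT codes per pixel.
#' @param lai A [lai_stack()].
#' @param params Compound parameter table; default built-in.
#' @param table Emission-rate table; default built-in.
#' @param compounds Species to simulate; default the terpene subset.
#' @param age_step_days Leaf-age interval (days).
#' @param chunk_size Pixels per processing chunk (no effect on values).
#' @param cap Incidence-ratio cap.
#' @param detail `"summary"` accumulates aggregates only; `"full"` also
#'   returns the complete `hours x pixels x compounds` flux array (small
#'   problems only).
#' @param theta,co2 Optional soil moisture / ambient CO2 (isoprene only).
#' @return Object of class `emission_run`; see Details in the package
#'   vignette. All fluxes in ug m-2 h-1.
#' @export
run_grid <- function(weather, terrain, pft, lai,
                     params = load_compound_params(),
                     table = load_emission_table(),
                     compounds = terpene_species(params),
                     age_step_days = 8, chunk_size = 256, cap = 3,
                     detail = c("summary", "full"),
                     theta = NULL, co2 = NULL) {
  detail <- match.arg(detail)
  p <- as.vector(pft)
  npix <- length(p)
  if (length(as.vector(terrain$slope)) != npix) {
    stop("PFT raster and terrain grids are not co-registered")
  }
  if (nrow(lai$values) != npix) stop("LAI stack does not match the grid")
  nt <- nrow(weather)
  if (nt > 1) {
    dt <- as.numeric(difftime(weather$timestamp[-1],
                              weather$timestamp[-nt], units = "hours"))
    if (any(abs(dt - 1) > 1e-6)) stop("weather must be hourly and gap-free")
  }
  cover <- pft_cover(p)
  forest <- cover$forest
  nforest <- sum(forest)

  lt <- as.POSIXlt(weather$timestamp)
  yday <- lt$yday + 1
  dmap <- match(yday, lai$days)
  if (any(is.na(dmap))) stop("weather period extends beyond the LAI stack")
  season <- classify_season(weather$timestamp)
  period <- classify_day_period(lt$hour)

  # temperature drivers are spatially uniform
  tK <- weather$temp_k
  t24 <- trailing_mean(tK, 24)
  t240 <- trailing_mean(tK, 240)

  # daily mean temperature for the leaf-age dynamics
  temp_daily <- vapply(split(tK, yday), mean, numeric(1))
  day_of <- as.integer(names(temp_daily))

  # leaf-age fractions per pixel per interval (deciduous path)
  steps <- seq(min(lai$days), max(lai$days), by = age_step_days)
  nst <- length(steps)
  frac <- array(0, c(npix, nst, 4))
  for (k in seq_len(nst)) {
    s <- steps[k]
    ci <- match(s, lai$days)
    pi_ <- match(max(s - age_step_days, lai$days[1]), lai$days)
    dsel <- day_of >= max(s - age_step_days, lai$days[1]) & day_of < s
    tt <- if (any(dsel)) mean(temp_daily[dsel]) else temp_daily[which.min(abs(day_of - s))]
    frac[, k, ] <- leaf_age_fractions_vec(lai$values[, ci], lai$values[, pi_],
                                          age_step_days, tt)
  }
  kmap <- findInterval(yday, steps)
  kmap[kmap < 1] <- 1

  specs <- lapply(compounds, function(cp) compound_spec(params, cp))
  names(specs) <- normalize_compound(compounds)
  classes <- vapply(specs, function(s) s$compound_class, character(1))
  ncomp <- length(specs)

  # per-compound constants and shared temperature response
  cce_con <- vapply(specs, calibrate_cce, numeric(1), pft = "needleleaf_conifer")
  cce_dec <- vapply(specs, calibrate_cce, numeric(1), pft = "broadleaf_deciduous")
  e_con <- vapply(names(specs), function(cp) epsilon(table, cp, "needleleaf_conifer"), numeric(1))
  e_dec <- vapply(names(specs), function(cp) epsilon(table, cp, "broadleaf_deciduous"), numeric(1))
  gt <- vapply(specs, function(s) gamma_t(tK, t24, t240, s), numeric(nt))
  if (nt == 1) gt <- matrix(gt, nrow = 1)

  # optional isoprene-only environmental factors (scalars)
  iso_extra <- rep(1, ncomp)
  iso <- which(names(specs) == "Isoprene")
  if (length(iso) == 1) {
    smp <- soil_co2_params()
    if (!is.null(theta)) iso_extra[iso] <- iso_extra[iso] * gamma_sm_isoprene(theta, smp)
    if (!is.null(co2)) iso_extra[iso] <- iso_extra[iso] * gamma_c_isoprene(co2, smp)
  }

  # per-pixel-step deciduous leaf-age factor per compound
  ga_dec <- vector("list", ncomp)
  f1 <- matrix(frac[, , 1], npix, nst); f2 <- matrix(frac[, , 2], npix, nst)
  f3 <- matrix(frac[, , 3], npix, nst); f4 <- matrix(frac[, , 4], npix, nst)
  for (i in seq_len(ncomp)) {
    s <- specs[[i]]
    ga_dec[[i]] <- f1 * s$a_new + f2 * s$a_gro + f3 * s$a_mat + f4 * s$a_old
  }

  sp <- solar_position(terrain$lat, terrain$lon, weather$timestamp,
                       terrain$utc_offset)
  slope <- as.vector(terrain$slope)
  aspect <- as.vector(terrain$aspect)

  cls_levels <- c("monoterpene", "sesquiterpene")
  seasons <- c("spring", "summer", "autumn", "winter")
  periods <- c("morning", "afternoon", "evening", "other")
  season_cols <- lapply(seasons, function(s) which(season == s))
  period_cols <- lapply(periods, function(s) which(period == s))

  pixel_sum <- matrix(0, npix, ncomp, dimnames = list(NULL, names(specs)))
  site_sum <- matrix(0, nt, ncomp, dimnames = list(NULL, names(specs)))
  px_season <- array(0, c(npix, 4, 2),
                     dimnames = list(NULL, seasons, cls_levels))
  px_period <- array(0, c(npix, 4, 2),
                     dimnames = list(NULL, periods, cls_levels))
  st_n <- st_s1 <- st_s2 <- matrix(0, 4, 2, dimnames = list(seasons, cls_levels))
  flux_full <- if (detail == "full") {
    array(0, c(nt, npix, ncomp), dimnames = list(NULL, NULL, names(specs)))
  } else NULL

  chunks <- split(seq_len(npix), ceiling(seq_len(npix) / chunk_size))
  for (idx in chunks) {
    nchunk <- length(idx)
    inc <- incidence_matrix(slope[idx], aspect[idx], sp$zenith, sp$azimuth,
                            cap = cap)
    ppfd_px <- inc * rep(weather$ppfd, each = nchunk)
    p24 <- t(apply(ppfd_px, 1, trailing_mean, n = 24))
    p240 <- t(apply(ppfd_px, 1, trailing_mean, n = 240))
    if (nt == 1) { p24 <- ppfd_px; p240 <- ppfd_px }
    # light-dependent core, shared across compounds
    pos <- p240 > 0
    alpha <- ifelse(pos, 0.004 - 0.0005 * log(pmax(p240, 1e-300)), 0)
    cp_ <- 0.0468 * p240^0.6 * exp(0.0005 * (p24 - P_STD_AVG))
    ax <- alpha * ppfd_px
    g_pldf <- ifelse(pos, pmax(cp_ * ax / sqrt(1 + ax^2), 0), 0)
    laiv <- lai$values[idx, dmap, drop = FALSE]
    cls_acc <- list(matrix(0, nchunk, nt), matrix(0, nchunk, nt))
    for (i in seq_len(ncomp)) {
      s <- specs[[i]]
      gp <- (1 - s$ldf) + s$ldf * g_pldf
      con_part <- cover$chi_conifer[idx] * cce_con[i] * e_con[i]
      dec_part <- (cover$chi_deciduous[idx] * cce_dec[i] * e_dec[i]) *
        ga_dec[[i]][idx, kmap, drop = FALSE]
      flux <- laiv * gp * (con_part + dec_part) *
        rep(gt[, i], each = nchunk) * iso_extra[i]
      pixel_sum[idx, i] <- pixel_sum[idx, i] + rowSums(flux)
      fr <- forest[idx]
      if (any(fr)) {
        site_sum[, i] <- site_sum[, i] + colSums(flux[fr, , drop = FALSE])
      }
      ci <- match(classes[i], cls_levels)
      if (!is.na(ci)) cls_acc[[ci]] <- cls_acc[[ci]] + flux
      if (!is.null(flux_full)) flux_full[, idx, i] <- t(flux)
    }
    fr <- forest[idx]
    for (ci in 1:2) {
      m <- cls_acc[[ci]]
      for (si in 1:4) {
        cols <- season_cols[[si]]
        if (length(cols) == 0) next
        sub <- m[, cols, drop = FALSE]
        px_season[idx, si, ci] <- px_season[idx, si, ci] + rowSums(sub)
        if (any(fr)) {
          x <- sub[fr, , drop = FALSE]
          st_n[si, ci] <- st_n[si, ci] + length(x)
          st_s1[si, ci] <- st_s1[si, ci] + sum(x)
          st_s2[si, ci] <- st_s2[si, ci] + sum(x^2)
        }
      }
      for (pi_ in 1:4) {
        cols <- period_cols[[pi_]]
        if (length(cols) == 0) next
        px_period[idx, pi_, ci] <- px_period[idx, pi_, ci] +
          rowSums(m[, cols, drop = FALSE])
      }
    }
  }

  for (si in 1:4) {
    nh <- length(season_cols[[si]])
    if (nh > 0) px_season[, si, ] <- px_season[, si, ] / nh
  }
  for (pi_ in 1:4) {
    nh <- length(period_cols[[pi_]])
    if (nh > 0) px_period[, pi_, ] <- px_period[, pi_, ] / nh
  }
  sd_mat <- sqrt(pmax(st_s2 - st_s1^2 / pmax(st_n, 1), 0) / pmax(st_n - 1, 1))
  class_season_stats <- data.frame(
    season = rep(seasons, times = 2),
    compound_class = rep(cls_levels, each = 4),
    n = as.vector(st_n), mean = as.vector(st_s1 / pmax(st_n, 1)),
    sd = as.vector(sd_mat)
  )
  class_season_stats <- class_season_stats[class_season_stats$n > 0, ]

  structure(list(
    compounds = data.frame(compound = names(specs), compound_class = classes,
                           row.names = NULL),
    timestamp = weather$timestamp,
    dim = dim(terrain$slope),
    forest = forest,
    pft = p,
    site_hourly = site_sum / max(nforest, 1),
    pixel_mean = pixel_sum / nt,
    pixel_season_class = px_season,
    pixel_period_class = px_period,
    class_season_stats = class_season_stats,
    flux = flux_full,
    meta = list(n_hours = nt, n_pixels = npix, n_forest = nforest,
                age_step_days = age_step_days, cap = cap,
                warmup_hours = min(nt, 240),
                period = range(weather$timestamp))
  ), class = "emission_run")
}

#' @export
print.emission_run <- function(x, ...) {
  cat(sprintf(
    "emission_run: %d hours x %d pixels (%d forest) x %d compounds\n",
    x$meta$n_hours, x$meta$n_pixels, x$meta$n_forest, nrow(x$compounds)))
  invisible(x)
}

#' Aggregate an emission run into compound-class totals
#'
#' Sums member species (including the "Others" pseudo-species) into
#' monoterpene, sesquiterpene and total-terpene series and maps.
#'
#' @param run An `emission_run`.
#' @return List with `site_hourly` (`hours x 3`) and `pixel_mean`
#'   (`pixels x 3`) matrices with columns `monoterpene_total`,
#'   `sesquiterpene_total`, `terpene_total`.
#' @export
aggregate_compound_classes <- function(run) {
  mono <- run$compounds$compound_class == "monoterpene"
  ses <- run$compounds$compound_class == "sesquiterpene"
  agg <- function(m) {
    out <- cbind(
      monoterpene_total = rowSums(m[, mono, drop = FALSE]),
      sesquiterpene_total = rowSums(m[, ses, drop = FALSE])
    )
    cbind(out, terpene_total = out[, 1] + out[, 2])
  }
  list(site_hourly = agg(run$site_hourly), pixel_mean = agg(run$pixel_mean))
}
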