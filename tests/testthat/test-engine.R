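test_that("pixel emission reproduces the standard-condition rate table", {
  tab <- load_emission_table()
  terp <- terpene_species()
  g1 <- setNames(rep(1, length(terp)), terp)
  # pure conifer at unit activity: each species at its tabulated rate
  f <- pixel_emission(g1, c(1, 0), tab)
  expect_equal(unname(f["Myrcene"]), 70)
  expect_equal(unname(f["b-Caryophyllene"]), 80)
  # 50/50 mixed cover averages the two columns
  f2 <- pixel_emission(g1, c(0.5, 0.5), tab)
  expect_equal(unname(f2["Myrcene"]), 50)
  # bare ground emits nothing
  expect_equal(unname(pixel_emission(g1, c(0, 0), tab)), rep(0, length(terp)))
  # linear in gamma
  expect_equal(pixel_emission(2 * g1, c(1, 0), tab), 2 * f)
  expect_error(pixel_emission(g1, c(0.7, 0.7), tab), "cover")
})

test_that("PFT cover fractions follow the mosaic rules", {
  pc <- pft_cover(c("needleleaf_conifer", "broadleaf_deciduous", "mixed",
                    "nonforest"))
  expect_equal(pc$chi_conifer, c(1, 0, 0.5, 0))
  expect_equal(pc$chi_deciduous, c(0, 1, 0.5, 0))
  expect_equal(pc$forest, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(pft_cover("savanna"), "unknown PFT")
})

test_that("grid engine matches a scalar composition of the modules on 1x1 grids", {
  sc <- small_scenario(seed = 3)
  w <- gen_weather(sc)[1:400, ]
  p <- load_compound_params()
  tab <- load_emission_table()
  days <- 1:366
  lai_daily <- 3 + 2 * sin(pi * pmin(days, 200) / 200)  # varying LAI
  tr <- flat_terrain_1px()
  tr$slope <- matrix(0.3, 1, 1)
  tr$aspect <- matrix(3 * pi / 4, 1, 1)

  # scalar oracle: corrected PPFD series -> rolling drivers -> gamma -> flux
  sp <- solar_position(tr$lat, tr$lon, w$timestamp, tr$utc_offset)
  fac <- incidence_factor(0.3, 3 * pi / 4, sp$zenith, sp$azimuth)
  met <- data.frame(timestamp = w$timestamp, temp_k = w$temp_k,
                    ppfd = w$ppfd * fac)
  met <- rolling_drivers(met)
  yday <- as.POSIXlt(w$timestamp)$yday + 1
  temp_daily <- vapply(split(w$temp_k, yday), mean, numeric(1))
  td_full <- rep(mean(w$temp_k), length(days))
  td_full[as.integer(names(temp_daily))] <- temp_daily
  las <- leaf_age_series(lai_daily, td_full, 8)

  compounds <- c("a-Pinene", "b-Caryophyllene")
  for (pft in c("needleleaf_conifer", "mixed")) {
    run <- run_grid(w, tr, matrix(pft, 1, 1), lai_stack(days, matrix(lai_daily, 1)),
                    compounds = compounds, detail = "full")
    for (cp in compounds) {
      s <- compound_spec(p, cp)
      cce_c <- calibrate_cce(s, "needleleaf_conifer")
      cce_d <- calibrate_cce(s, "broadleaf_deciduous")
      hours <- c(10, 180, 250, 399)
      for (h in hours) {
        mh <- list(t = met$temp_k[h], ppfd = met$ppfd[h], t24 = met$t24[h],
                   t240 = met$t240[h], p24 = met$p24[h], p240 = met$p240[h])
        k <- findInterval(yday[h], las$day)
        fr <- unlist(las[k, c("f_new", "f_gro", "f_mat", "f_sen")])
        laiv <- lai_daily[yday[h]]
        g_c <- suppressWarnings(gamma_total(mh, laiv, fr, s,
                                            "needleleaf_conifer", cce = cce_c))
        g_d <- suppressWarnings(gamma_total(mh, laiv, fr, s,
                                            "broadleaf_deciduous", cce = cce_d))
        chi <- if (pft == "needleleaf_conifer") c(1, 0) else c(0.5, 0.5)
        expected <- g_c$gamma_total * epsilon(tab, cp, "needleleaf_conifer") * chi[1] +
          g_d$gamma_total * epsilon(tab, cp, "broadleaf_deciduous") * chi[2]
        expect_equal(unname(run$flux[h, 1, cp]), unname(expected),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("engine output is linear in the emission table and deterministic", {
  sc <- small_scenario(seed = 5, nrow = 4, ncol = 4)
  dat <- gen_scenario_data(sc)
  w <- dat$weather[1:120, ]
  lai <- const_lai(16)
  r1 <- run_grid(w, dat$terrain, dat$pft, lai)
  r2 <- run_grid(w, dat$terrain, dat$pft, lai)
  expect_identical(r1$pixel_mean, r2$pixel_mean)  # bit-stable rerun
  # chunk size must not affect values
  r3 <- run_grid(w, dat$terrain, dat$pft, lai, chunk_size = 3)
  expect_equal(r3$pixel_mean, r1$pixel_mean, tolerance = 1e-12)
  # doubling every epsilon doubles every flux
  tab2 <- load_emission_table()
  tab2$needleleaf_conifer <- 2 * tab2$needleleaf_conifer
  tab2$broadleaf_deciduous <- 2 * tab2$broadleaf_deciduous
  r4 <- run_grid(w, dat$terrain, dat$pft, lai, table = tab2)
  expect_equal(r4$pixel_mean, 2 * r1$pixel_mean, tolerance = 1e-12)
  # non-forest pixels emit exactly zero
  nf <- !r1$forest
  if (any(nf)) expect_true(all(r1$pixel_mean[nf, ] == 0))
  expect_true(all(r1$pixel_mean >= 0))
})

test_that("night flux for a light-dependent species falls to its
           light-independent share", {
  tr <- flat_terrain_1px()
  ts <- seq(as.POSIXct("2020-06-21 00:00:00", tz = "UTC"), by = "hour",
            length.out = 24)
  w <- data.frame(timestamp = ts, temp_k = 303, ppfd = 0)
  sp <- solar_position(tr$lat, tr$lon, ts, tr$utc_offset)
  w$ppfd[sp$zenith < pi / 2] <- 1500
  run <- run_grid(w, tr, matrix("needleleaf_conifer", 1, 1),
                  const_lai(1, 5), compounds = "t-b-Ocimene", detail = "full")
  night <- which(sp$zenith >= pi / 2)
  day <- which(sp$zenith < pi / 2)
  expect_lt(max(run$flux[night, 1, 1]), min(run$flux[day[-1], 1, 1]))
})

test_that("class aggregation sums members and dominates every member", {
  sc <- small_scenario(seed = 9, nrow = 3, ncol = 3)
  dat <- gen_scenario_data(sc)
  w <- dat$weather[1:72, ]
  run <- run_grid(w, dat$terrain, dat$pft, const_lai(9))
  agg <- aggregate_compound_classes(run)
  mono <- run$compounds$compound_class == "monoterpene"
  expect_equal(agg$pixel_mean[, "monoterpene_total"],
               rowSums(run$pixel_mean[, mono]))
  expect_equal(agg$pixel_mean[, "terpene_total"],
               agg$pixel_mean[, "monoterpene_total"] +
                 agg$pixel_mean[, "sesquiterpene_total"])
  expect_true(all(agg$pixel_mean[, "terpene_total"] >=
                    apply(run$pixel_mean, 1, max) - 1e-12))
})

test_that("engine rejects inconsistent inputs", {
  sc <- small_scenario(seed = 5, nrow = 4, ncol = 4)
  dat <- gen_scenario_data(sc)
  w <- dat$weather[1:48, ]
  expect_error(run_grid(w, dat$terrain, matrix("mixed", 2, 2), const_lai(4)),
               "co-registered")
  expect_error(run_grid(w, dat$terrain, dat$pft, const_lai(5)),
               "LAI stack")
  w2 <- w[c(1:10, 12:48), ]
  expect_error(run_grid(w2, dat$terrain, dat$pft, const_lai(16)), "hourly")
  expect_error(run_grid(w, dat$terrain, dat$pft, const_lai(16, days = 200:366)),
               "beyond the LAI stack")
})
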