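test_that("NDVI band arithmetic and the LAI regression behave", {
  expect_equal(ndvi_from_bands(0.05, 0.45), 0.8)
  expect_equal(ndvi_from_bands(0.3, 0.3), 0)
  expect_equal(ndvi_from_bands(0, 0.3), 1)
  expect_true(is.na(ndvi_from_bands(0, 0)))
  expect_equal(ndvi_to_lai(0), 0.8384)
  expect_equal(ndvi_to_lai(0.5), 4.21525)
  expect_equal(ndvi_to_lai(-0.5), 0)  # floored
  expect_error(ndvi_to_lai(1.2), "ndvi")
  # affine and order-preserving on the valid range
  x <- sort(runif(50, -0.1, 1))
  expect_true(all(diff(ndvi_to_lai(x)) >= 0))
})

test_that("Hampel repair flags spikes and leaves clean series untouched", {
  x <- rep(5, 31); x[16] <- 12
  h <- hampel_clean(x)
  expect_equal(h$values, rep(5, 31))
  expect_equal(which(h$outliers), 16)
  # monotone ramp: no outliers, identity
  r <- hampel_clean(seq(0, 3, length.out = 40))
  expect_false(any(r$outliers))
  expect_equal(r$values, seq(0, 3, length.out = 40))
  expect_error(hampel_clean(1:5, window = 3), "too short")
})

test_that("Hampel recovers >= 90% of injected spikes on a seeded NDVI series", {
  set.seed(101)
  n <- 400
  truth <- 0.6 + 0.15 * sin(seq(0, 4 * pi, length.out = n))
  sigma <- 0.02
  y <- truth + rnorm(n, 0, sigma)
  # ~5% isolated spikes well clear of the detection threshold (the MAD
  # estimate from a 7-point window is itself noisy, so a spike at exactly
  # the threshold is a coin flip by construction)
  inj <- seq(7, n, by = 20)
  y[inj] <- y[inj] - 3 * sigma * runif(length(inj), 2, 4)
  h <- hampel_clean(y)
  hit <- mean(inj %in% which(h$outliers))
  expect_gte(hit, 0.9)
})

test_that("double-logistic fit recovers known parameters", {
  truth <- c(mn = 1, mx = 5, sos = 120, rsp = 0.1, eos = 290, rsw = 0.08)
  doy <- seq(5, 360, by = 8)
  y <- double_logistic(doy, truth["mn"], truth["mx"], truth["sos"],
                       truth["rsp"], truth["eos"], truth["rsw"])
  fit <- double_logistic_fit(doy, y)
  expect_equal(fit$method, "double_logistic")
  expect_equal(unname(fit$params[names(truth)]), unname(truth),
               tolerance = 0.01)
  # with noise: daily RMSE against truth below the noise sd
  set.seed(7)
  sigma <- 0.3
  fitn <- double_logistic_fit(doy, y + rnorm(length(y), 0, sigma))
  daily_truth <- double_logistic(1:365, truth["mn"], truth["mx"], truth["sos"],
                                 truth["rsp"], truth["eos"], truth["rsw"])
  rmse <- sqrt(mean((fitn$fitted - daily_truth)^2))
  expect_lt(rmse, sigma)
})

test_that("degenerate series fall back to interpolation with a warning", {
  doy <- seq(5, 360, by = 10)
  expect_warning(fit <- double_logistic_fit(doy, rep(3, length(doy))),
                 "fell back")
  expect_equal(fit$method, "linear")
  expect_equal(fit$fitted, rep(3, 365))
  expect_error(double_logistic_fit(1:5, 1:5), "at least 10")
})

test_that("leaf-age fractions follow the three-case LAI-change rule", {
  expect_equal(leaf_age_fractions(3, 3, 8, 295),
               c(f_new = 0, f_gro = 0.1, f_mat = 0.8, f_sen = 0.1))
  expect_equal(leaf_age_fractions(1, 2, 8, 295),
               c(f_new = 0, f_gro = 0, f_mat = 0.5, f_sen = 0.5))
  # growth case, t = 8 > ti = 5 (Tt = 300): Fnew = (ti/t)(1 - p/c)
  f <- leaf_age_fractions(2, 1, 8, 300)
  expect_equal(unname(f["f_new"]), (5 / 8) * 0.5)
  expect_equal(unname(f["f_mat"]), 0.5)        # t <= tm = 11.5
  expect_equal(unname(f["f_gro"]), 1 - 0.5 - 0.3125)
  expect_equal(unname(f["f_sen"]), 0)
  # growth case within ti: Fnew = 1 - p/c
  f2 <- leaf_age_fractions(2, 1, 4, 300)
  expect_equal(unname(f2["f_new"]), 0.5)
})

test_that("bud-break timing is continuous and capped above 303 K", {
  expect_equal(bud_break_ti(300), 5)
  expect_equal(bud_break_ti(304), 2.9)
  expect_equal(bud_break_ti(303), 2.9)  # 5 + 0.7*(300-303) = 2.9: continuous
  expect_equal(bud_break_ti(290), 12)
})

test_that("leaf-age fractions sum to 1 and are non-negative (property sweep)", {
  set.seed(11)
  n <- 10000
  lai_c <- runif(n, 0, 7)
  lai_p <- runif(n, 0, 7)
  tt <- runif(n, 260, 310)
  td <- sample(c(4, 8, 16), n, replace = TRUE)
  for (i in seq_len(200)) {  # scalar spot checks against the vector path
    f <- leaf_age_fractions(lai_c[i], lai_p[i], td[i], tt[i])
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_true(all(f >= 0))
  }
  fv <- terpflux:::leaf_age_fractions_vec(lai_c, lai_p, 8, 295)
  expect_equal(unname(rowSums(fv)), rep(1, n), tolerance = 1e-9)
  expect_true(all(fv >= 0))
})

test_that("evergreen canopies keep a unit leaf-age factor in all seasons", {
  expect_equal(evergreen_gamma_a(), 1)
  p <- load_compound_params()
  s <- compound_spec(p, "a-Pinene")
  expect_equal(gamma_a(NULL, s, "needleleaf_conifer"), 1)
  # deciduous canopies are routed through the fraction-weighted path
  f <- leaf_age_fractions(3, 3, 8, 295)
  expect_equal(gamma_a(f, s, "broadleaf_deciduous"),
               0.1 * 1.8 + 0.8 * 1.0 + 0.1 * 1.05)
})
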