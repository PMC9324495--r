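test_that("light response matches limits and a hand evaluation", {
  # dark limit: only the light-independent share remains
  expect_equal(gamma_p(0, 200, 200, 0.6), 0.4)
  # light-independent species are insensitive to light
  expect_equal(gamma_p(1800, 300, 250, 0), 1.0)
  # hand evaluation at standard drivers, ldf = 1:
  # alpha = 0.004 - 0.0005 ln(200); Cp = 0.0468 * 200^0.6
  alpha <- 0.004 - 0.0005 * log(200)
  cp <- 0.0468 * 200^0.6
  g_hand <- cp * alpha * 1500 / sqrt(1 + (alpha * 1500)^2)
  expect_equal(gamma_p(1500, 200, 200, 1), g_hand)
  expect_equal(g_hand, 1.008162, tolerance = 1e-6)
  expect_error(gamma_p(-1, 200, 200, 0.5), "non-negative")
  expect_warning(g0 <- gamma_p(100, 0, 0, 0.6), "no light history")
  expect_equal(g0, 0.4)
})

test_that("light response is non-decreasing in instantaneous PPFD", {
  ppfd <- seq(0, 2500, by = 25)
  g <- gamma_p(ppfd, 200, 200, 0.8)
  expect_true(all(diff(g) >= -1e-12))
})

test_that("temperature response matches limits and a hand evaluation", {
  p <- load_compound_params()
  mono <- compound_spec(p, "Limonene")  # ldf 0.2
  lif_only <- list(beta = 0.10, ldf = 0, ct1 = 80, ceo = 1.83)
  expect_equal(gamma_t(303, 297, 297, lif_only), 1.0)
  expect_equal(gamma_t(313, 297, 297, lif_only), exp(1))
  # step-through of the light-dependent branch at standard drivers
  x <- (1 / 0.0083) * (1 / 313 - 1 / 303)
  eopt <- 1.83
  g_hand <- eopt * 230 * exp(80 * x) / (230 - 80 * (1 - exp(230 * x)))
  expect_equal(gamma_t_ldf(303, 297, 297, 80, 1.83), g_hand)
  expect_equal(g_hand, 0.9872, tolerance = 1e-4)
  # blended response at ldf 0.2
  expect_equal(gamma_t(303, 297, 297, mono), 0.8 * 1 + 0.2 * g_hand)
  expect_error(gamma_t(30, 297, 297, mono), "Kelvin")
})

test_that("light-independent response is strictly increasing in T; the
           light-dependent one is unimodal with its optimum near Topt", {
  tt <- seq(270, 320, by = 0.25)
  expect_true(all(diff(gamma_t_lif(tt, 0.1)) > 0))
  for (t240 in c(285, 297, 305)) {
    g <- gamma_t_ldf(tt, t240, t240, 80, 1.83)
    peak <- tt[which.max(g)]
    topt <- 313 + 0.6 * (t240 - 297)
    expect_lt(abs(peak - topt), 2)
    # unimodal: increases then decreases
    d <- diff(g)
    expect_true(all(d[tt[-1] < peak - 0.5] > 0))
    expect_true(all(d[tt[-length(tt)] > peak + 0.5] < 0))
  }
})

test_that("sesquiterpene/monoterpene temperature-response ratio grows with T", {
  p <- load_compound_params()
  ses <- compound_spec(p, "b-Caryophyllene")
  mono <- compound_spec(p, "a-Pinene")
  tt <- seq(280, 310, by = 2)
  ratio <- gamma_t(tt, 297, 297, ses) / gamma_t(tt, 297, 297, mono)
  expect_true(all(diff(ratio) > 0))
})

test_that("leaf-age factor is the dot product of fractions and coefficients", {
  p <- load_compound_params()
  mono <- compound_spec(p, "Myrcene")
  f <- c(f_new = 0, f_gro = 0.1, f_mat = 0.8, f_sen = 0.1)
  expect_equal(gamma_a(f, mono), 0.18 + 0.8 + 0.105)
  expect_equal(gamma_a(c(0, 0, 1, 0), mono), 1.0)
  expect_equal(gamma_a(f, mono, "needleleaf_conifer"), 1.0)
  expect_error(gamma_a(c(0.5, 0.5, 0.5, 0), mono), "sum to 1")
})

test_that("soil-moisture ramp and CO2 response behave at their anchors", {
  sp <- soil_co2_params(theta_w = 0.1)
  expect_equal(gamma_sm_isoprene(0.1, sp), 0)
  expect_equal(gamma_sm_isoprene(0.13, sp), 0.5)
  expect_equal(gamma_sm_isoprene(0.4, sp), 1)
  expect_equal(gamma_c_isoprene(400, sp), 1.0)
  # limits: Ci -> 0 gives ISmax, Ci -> Inf gives 0
  expect_equal(gamma_c_isoprene(1e-9, sp), sp$is_max)
  expect_lt(gamma_c_isoprene(1e9, sp), 1e-3)
  expect_error(gamma_c_isoprene(-1, sp), "positive")
})

test_that("CCE calibration pins total activity at 1 for every species and PFT", {
  p <- load_compound_params()
  std <- standard_conditions()
  met <- std_met()
  for (cp in p$compound) {
    s <- compound_spec(p, cp)
    for (pft in c("needleleaf_conifer", "broadleaf_deciduous")) {
      af <- gamma_total(met, std$lai_v, std$leaf_age_fractions, s, pft)
      expect_equal(af$gamma_total, 1, tolerance = 1e-9)
    }
  }
  # idempotent: recalibration returns the same coefficient
  s <- compound_spec(p, "Sabinene")
  expect_identical(calibrate_cce(s), calibrate_cce(s))
  # deciduous monoterpene coefficient decomposes as expected
  gp <- gamma_p(std$p_inst, 200, 200, s$ldf)
  gt <- gamma_t(303, 297, 297, s)
  expect_equal(calibrate_cce(s), 1 / (5 * gp * gt * 1.085))
})

test_that("total activity is multiplicative, linear in LAIv and zero without foliage", {
  p <- load_compound_params()
  s <- compound_spec(p, "a-Pinene")
  met <- list(t = 298, ppfd = 900, t24 = 295, t240 = 293, p24 = 180, p240 = 210)
  f <- leaf_age_fractions(4, 3.5, 8, 293)
  a1 <- gamma_total(met, 3, f, s)
  expect_equal(a1$gamma_total,
               a1$cce * a1$lai_v * a1$gamma_p * a1$gamma_t * a1$gamma_a *
                 a1$gamma_sm * a1$gamma_c, tolerance = 1e-12)
  a2 <- gamma_total(met, 6, f, s)
  expect_equal(a2$gamma_total, 2 * a1$gamma_total, tolerance = 1e-12)
  a0 <- gamma_total(met, 0, f, s)
  expect_equal(a0$gamma_total, 0)
})

test_that("all activity components are non-negative over random valid inputs", {
  set.seed(23)
  p <- load_compound_params()
  n <- 10000
  t <- runif(n, 260, 315); t24 <- runif(n, 260, 315); t240 <- runif(n, 260, 315)
  ppfd <- runif(n, 0, 2500); p24 <- runif(n, 1, 600); p240 <- runif(n, 1, 600)
  for (cp in c("a-Pinene", "b-Caryophyllene", "Isoprene")) {
    s <- compound_spec(p, cp)
    expect_true(all(gamma_p(ppfd, p24, p240, s$ldf) >= 0))
    expect_true(all(gamma_t(t, t24, t240, s) >= 0))
  }
  expect_true(all(gamma_sm_isoprene(runif(n)) >= 0))
})
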