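# Emission activity factors: light (gamma_p), temperature (gamma_t),
# leaf age (gamma_a), soil moisture and CO2 (isoprene only), and the
# canopy-environment-coefficient calibration that pins the total activity
# at 1 under standard conditions.

T_STD_INST <- 303   # standard instantaneous leaf/air temperature (K)
T_STD_AVG <- 297    # standard 24 h / 240 h average temperature (K)
P_STD_AVG <- 200    # standard 24 h / 240 h average PPFD, sun leaves

#' Light-responsive activity factor
#'
#' Blend of a light-independent share `(1 - LDF)` and the light-dependent
#' response `gamma_PLDF = Cp * alpha * PPFD / sqrt(1 + (alpha * PPFD)^2)`,
#' where `alpha = 0.004 - 0.0005 ln(P240)` and
#' `Cp = 0.0468 * P240^0.6 * exp(0.0005 (P24 - 200))`. The light history
#' enters through the trailing 24 h / 240 h mean PPFD.
#'
#' @param ppfd Instantaneous PPFD (umol m-2 s-1).
#' @param p24,p240 Trailing 24 h / 240 h mean PPFD.
#' @param ldf Light-dependent fraction of the compound (0-1).
#' @return Dimensionless factor, >= 0.
#' @export
gamma_p <- function(ppfd, p24, p240, ldf) {
  if (any(ppfd < 0) || any(p24 < 0) || any(p240 < 0)) {
    stop("PPFD drivers must be non-negative")
  }
  g_pldf <- gamma_pldf(ppfd, p24, p240)
  pmax((1 - ldf) + ldf * g_pldf, 0)
}

# light-dependent part; zero (with a warning) when there is no light history
gamma_pldf <- function(ppfd, p24, p240) {
  n <- max(length(ppfd), length(p24), length(p240))
  ppfd <- rep_len(ppfd, n); p24 <- rep_len(p24, n); p240 <- rep_len(p240, n)
  out <- numeric(n)
  dark <- p240 <= 0
  if (any(dark)) {
    warning("P240 = 0: no light history, light-dependent part set to 0")
  }
  ok <- !dark
  if (any(ok)) {
    alpha <- 0.004 - 0.0005 * log(p240[ok])
    cp <- 0.0468 * p240[ok]^0.6 * exp(0.0005 * (p24[ok] - P_STD_AVG))
    x <- alpha * ppfd[ok]
    out[ok] <- pmax(cp * x / sqrt(1 + x^2), 0)
  }
  out
}

#' Temperature-responsive activity factor
#'
#' Blend `(1 - LDF) * gamma_TLIF + LDF * gamma_TLDF` of the
#' light-independent exponential response `exp(beta (T - 303))` and the
#' light-dependent optimum-shaped response whose optimum temperature and
#' height shift with the trailing 24 h / 240 h temperature history.
#'
#' @param t Instantaneous leaf/air temperature (K).
#' @param t24,t240 Trailing 24 h / 240 h mean temperature (K).
#' @param spec Compound parameter row ([compound_spec()]) or a list with
#'   `beta`, `ldf`, `ct1`, `ceo`.
#' @return Dimensionless factor, >= 0.
#' @export
gamma_t <- function(t, t24, t240, spec) {
  if (any(t <= 200) || any(t24 <= 200) || any(t240 <= 200)) {
    stop("temperatures must be in Kelvin (> 200 K)")
  }
  (1 - spec$ldf) * gamma_t_lif(t, spec$beta) +
    spec$ldf * gamma_t_ldf(t, t24, t240, spec$ct1, spec$ceo)
}

#' Light-independent temperature response
#' @param t Temperature (K).
#' @param beta Temperature sensitivity (1/K).
#' @return `exp(beta * (t - 303))`.
#' @export
gamma_t_lif <- function(t, beta) {
  exp(beta * (t - T_STD_INST))
}

#' Light-dependent temperature response
#'
#' `Eopt * 230 exp(CT1 x) / (230 - CT1 (1 - exp(230 x)))` with
#' `x = (1/0.0083) (1/Topt - 1/T)`, `Topt = 313 + 0.6 (T240 - 297)` and
#' `Eopt = Ceo exp(0.05 (T24 + T240 - 2*297))`.
#'
#' @param t,t24,t240 Instantaneous and trailing mean temperatures (K).
#' @param ct1,ceo Empirical compound coefficients.
#' @return Dimensionless response, >= 0.
#' @export
gamma_t_ldf <- function(t, t24, t240, ct1, ceo) {
  topt <- 313 + 0.6 * (t240 - T_STD_AVG)
  x <- (1 / 0.0083) * (1 / topt - 1 / t)
  eopt <- ceo * exp(0.05 * (t24 + t240 - 2 * T_STD_AVG))
  eopt * 230 * exp(ct1 * x) / (230 - ct1 * (1 - exp(230 * x)))
}

#' Leaf-age activity factor
#'
#' Weighted sum of the compound's leaf-age coefficients over the canopy
#' age-class fractions. Evergreen conifer canopies short-circuit to 1.
#'
#' @param fractions Named vector from [leaf_age_fractions()].
#' @param spec Compound parameter row (`a_new`, `a_gro`, `a_mat`, `a_old`).
#' @param pft PFT of the canopy; `"needleleaf_conifer"` returns 1.
#' @return Dimensionless factor.
#' @export
gamma_a <- function(fractions, spec, pft = "broadleaf_deciduous") {
  if (identical(pft, "needleleaf_conifer")) return(evergreen_gamma_a())
  if (abs(sum(fractions) - 1) > 1e-6 || any(fractions < 0)) {
    stop("leaf-age fractions must be non-negative and sum to 1")
  }
  sum(fractions * c(spec$a_new, spec$a_gro, spec$a_mat, spec$a_old))
}

#' Soil-moisture activity factor (isoprene)
#'
#' Piecewise-linear ramp in volumetric soil moisture: 0 below the wilting
#' point, 1 above `theta_w + delta_theta1`, linear between.
#'
#' @param theta Volumetric soil moisture (m3 m-3).
#' @param params [soil_co2_params()].
#' @return Factor in `[0, 1]`.
#' @export
gamma_sm_isoprene <- function(theta, params = soil_co2_params()) {
  pmin(pmax((theta - params$theta_w) / params$delta_theta1, 0), 1)
}

#' CO2 activity factor (isoprene)
#'
#' `ISmax (1 - Ci^h / (Cstar^h + Ci^h))` with `Ci = 0.7 x` ambient CO2;
#' equals 1 at the reference ambient level with the default calibration.
#'
#' @param ambient_co2 Ambient CO2 (ppm).
#' @param params [soil_co2_params()].
#' @return Dimensionless factor.
#' @export
gamma_c_isoprene <- function(ambient_co2, params = soil_co2_params()) {
  if (any(ambient_co2 <= 0)) stop("ambient CO2 must be positive")
  ci <- params$ci_fraction * ambient_co2
  params$is_max * (1 - ci^params$h / (params$c_star^params$h + ci^params$h))
}

#' Calibrate the canopy environment coefficient
#'
#' `CCE` is fixed so the total activity factor is exactly 1 at standard
#' conditions. Because the leaf-age factor of an evergreen canopy is pinned
#' at 1 while a deciduous canopy at standard composition is not, `CCE` is
#' calibrated per compound and per PFT leaf-age mode, so the unity property
#' holds for both canopy types.
#'
#' @param spec Compound parameter row.
#' @param pft PFT whose leaf-age path the coefficient is calibrated for.
#' @param std Standard conditions, [standard_conditions()].
#' @return The scalar `cce`.
#' @export
calibrate_cce <- function(spec, pft = "broadleaf_deciduous",
                          std = standard_conditions()) {
  gp <- gamma_p(std$p_inst, std$p_avg_sun, std$p_avg_sun, spec$ldf)
  gt <- gamma_t(std$t_inst, std$t_avg, std$t_avg, spec)
  ga <- gamma_a(std$leaf_age_fractions, spec, pft)
  denom <- std$lai_v * gp * gt * ga
  if (!is.finite(denom) || denom <= 0) {
    stop("standard-condition activity component is zero; cannot calibrate CCE")
  }
  1 / denom
}

#' Total emission activity factor
#'
#' `gamma = CCE * LAIv * gamma_P * gamma_T * gamma_A * gamma_SM * gamma_C`.
#' Soil-moisture and CO2 responses apply to isoprene only and default to 1
#' (they are held at 1 for all terpenes).
#'
#' @param met List or one-row data frame with `t`, `ppfd`, `t24`, `t240`,
#'   `p24`, `p240`.
#' @param lai_v Effective LAI.
#' @param fractions Leaf-age fractions (ignored for conifer canopies).
#' @param spec Compound parameter row.
#' @param pft Canopy PFT.
#' @param cce Precomputed coefficient; calibrated on the fly when `NULL`.
#' @param theta Volumetric soil moisture; `NULL` leaves the factor at 1.
#' @param co2 Ambient CO2 (ppm); `NULL` leaves the factor at 1.
#' @param sm_params [soil_co2_params()] for the isoprene paths.
#' @return List of class `activity_factors` with each component, `cce`,
#'   `lai_v` and the product `gamma_total`.
#' @export
gamma_total <- function(met, lai_v, fractions, spec,
                        pft = "broadleaf_deciduous", cce = NULL,
                        theta = NULL, co2 = NULL,
                        sm_params = soil_co2_params()) {
  if (is.null(cce)) cce <- calibrate_cce(spec, pft)
  gp <- gamma_p(met$ppfd, met$p24, met$p240, spec$ldf)
  gt <- gamma_t(met$t, met$t24, met$t240, spec)
  ga <- gamma_a(fractions, spec, pft)
  is_iso <- identical(normalize_compound(spec$compound), "Isoprene")
  gsm <- if (is_iso && !is.null(theta)) gamma_sm_isoprene(theta, sm_params) else 1
  gc_ <- if (is_iso && !is.null(co2)) gamma_c_isoprene(co2, sm_params) else 1
  structure(list(gamma_p = gp, gamma_t = gt, gamma_a = ga,
                 gamma_sm = gsm, gamma_c = gc_, cce = cce, lai_v = lai_v,
                 gamma_total = cce * lai_v * gp * gt * ga * gsm * gc_),
            class = "activity_factors")
}

#' @export
print.activity_factors <- function(x, ...) {
  cat("emission activity factors:\n")
  for (nm in c("gamma_p", "gamma_t", "gamma_a", "gamma_sm", "gamma_c",
               "cce", "lai_v", "gamma_total")) {
    cat(sprintf("  %-11s %s\n", nm,
                paste(signif(x[[nm]], 6), collapse = " ")))
  }
  invisible(x)
}
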