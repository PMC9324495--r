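# NDVI -> LAI phenology: band arithmetic, the empirical LAI regression,
# Hampel outlier repair, double-logistic smoothing, and the leaf-age
# fraction dynamics driven by LAI change.

#' NDVI from red and near-infrared reflectance
#'
#' @param red,nir Surface reflectance (0-1).
#' @return `(nir - red) / (nir + red)`; `NA` where both bands are zero.
#' @export
ndvi_from_bands <- function(red, nir) {
  s <- red + nir
  out <- ifelse(s > 0, (nir - red) / s, NA_real_)
  out
}

#' Leaf area index from NDVI
#'
#' Empirical linear regression calibrated for South Korean forests:
#' `LAI = 6.7537 * NDVI + 0.8384`, floored at zero.
#'
#' @param ndvi NDVI in `[-1, 1]`.
#' @return LAI (m2 m-2).
#' @export
ndvi_to_lai <- function(ndvi) {
  if (any(ndvi < -1 | ndvi > 1, na.rm = TRUE)) {
    stop("ndvi outside [-1, 1]")
  }
  pmax(6.7537 * ndvi + 0.8384, 0)
}

#' Hampel outlier repair of a time series
#'
#' Points deviating from the rolling median by more than
#' `nsigma * 1.4826 * MAD` of their window are replaced by the rolling
#' median. Wraps `pracma::hampel`.
#'
#' @param x Numeric series.
#' @param window Half-width of the window in samples.
#' @param nsigma MAD multiplier threshold.
#' @return List with `values` (repaired series) and `outliers` (logical mask
#'   of replaced points).
#' @export
hampel_clean <- function(x, window = 3, nsigma = 3) {
  n <- length(x)
  if (n <= 2 * window) {
    stop("series too short for the Hampel window")
  }
  # reflect the series ends so the first/last `window` points get a full
  # window too (the plain filter leaves them unexamined)
  pad <- c(x[(window + 1):2], x, x[(n - 1):(n - window)])
  h <- pracma::hampel(pad, k = window, t0 = nsigma)
  y <- h$y[(window + 1):(window + n)]
  mask <- rep(FALSE, n)
  ind <- h$ind - window
  ind <- ind[ind >= 1 & ind <= n]
  mask[ind] <- TRUE
  list(values = y, outliers = mask)
}

#' Double-logistic seasonal curve
#'
#' `f(t) = mn + (mx - mn) * (1/(1+exp(-rsp*(t-sos))) +
#'         1/(1+exp(rsw*(t-eos))) - 1)`
#'
#' @param t Day of year.
#' @param mn,mx Winter baseline and summer plateau.
#' @param sos,eos Start/end of season (inflection days).
#' @param rsp,rsw Spring and autumn rate parameters (1/day).
#' @return Curve values at `t`.
#' @export
double_logistic <- function(t, mn, mx, sos, rsp, eos, rsw) {
  mn + (mx - mn) * (1 / (1 + exp(-rsp * (t - sos))) +
                      1 / (1 + exp(rsw * (t - eos))) - 1)
}

#' Fit a double-logistic curve to a seasonal series
#'
#' Least-squares fit (Levenberg-Marquardt, `minpack.lm::nlsLM`) with
#' initial values from the 5th/95th percentiles and half-amplitude
#' crossings, and box bounds keeping `sos < eos`. Degenerate series (near
#' zero seasonal amplitude) and non-convergent fits fall back to linear
#' interpolation with a warning.
#'
#' @param doy Day-of-year of the observations.
#' @param y Observed values (e.g. LAI).
#' @param days Days at which to evaluate the smoothed curve
#'   (default 1..365).
#' @param min_amplitude Amplitude below which the fit is declared
#'   degenerate.
#' @return List with `params` (named vector or `NULL`), `fitted` (values at
#'   `days`), `days`, and `method` (`"double_logistic"` or `"linear"`).
#' @export
double_logistic_fit <- function(doy, y, days = 1:365, min_amplitude = 0.05) {
  ok <- is.finite(y)
  doy <- doy[ok]; y <- y[ok]
  if (length(y) < 10) stop("need at least 10 valid observations")
  q <- quantile(y, c(0.05, 0.95), names = FALSE)
  mn0 <- q[1]; mx0 <- q[2]
  if ((mx0 - mn0) < min_amplitude) {
    return(dl_fallback(doy, y, days, "degenerate (flat) series"))
  }
  half <- (mn0 + mx0) / 2
  above <- y >= half
  sos0 <- if (any(above)) min(doy[above]) else quantile(doy, 0.3, names = FALSE)
  eos0 <- if (any(above)) max(doy[above]) else quantile(doy, 0.7, names = FALSE)
  if (sos0 >= eos0) return(dl_fallback(doy, y, days, "no seasonal course"))
  start <- list(mn = mn0, mx = mx0, sos = sos0, rsp = 0.1, eos = eos0,
                rsw = 0.1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ double_logistic(doy, mn, mx, sos, rsp, eos, rsw),
      start = start,
      lower = c(mn = -5, mx = -5, sos = 1, rsp = 1e-3, eos = 30, rsw = 1e-3),
      upper = c(mn = 20, mx = 20, sos = 330, rsp = 2, eos = 366, rsw = 2),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(dl_fallback(doy, y, days, "non-convergence"))
  p <- coef(fit)
  if (p["mx"] < p["mn"] || p["sos"] >= p["eos"]) {
    return(dl_fallback(doy, y, days, "implausible parameters"))
  }
  list(params = p,
       fitted = double_logistic(days, p["mn"], p["mx"], p["sos"], p["rsp"],
                                p["eos"], p["rsw"]),
       days = days, method = "double_logistic")
}

dl_fallback <- function(doy, y, days, reason) {
  warning("double-logistic fit fell back to linear interpolation: ", reason)
  f <- approx(doy, y, xout = days, rule = 2)$y
  list(params = NULL, fitted = f, days = days, method = "linear")
}

#' Smooth a per-pixel NDVI series into daily LAI
#'
#' The full phenology chain for one pixel: Hampel repair of the NDVI series
#' (which also removes monsoon-depressed values), conversion to LAI, and
#' double-logistic smoothing to a daily series.
#'
#' @param doy Day-of-year of the NDVI observations.
#' @param ndvi NDVI observations.
#' @param days Evaluation days (default 1..365).
#' @param window,nsigma Hampel parameters.
#' @return As [double_logistic_fit()], plus `outliers` (the Hampel mask) and
#'   `lai_obs` (the repaired LAI observations).
#' @export
smooth_lai <- function(doy, ndvi, days = 1:365, window = 3, nsigma = 3) {
  hc <- hampel_clean(ndvi, window = window, nsigma = nsigma)
  lai <- ndvi_to_lai(hc$values)
  fit <- suppressWarnings(double_logistic_fit(doy, lai, days = days))
  fit$fitted <- pmax(fit$fitted, 0)
  fit$outliers <- hc$outliers
  fit$lai_obs <- lai
  fit
}

#' Leaf-age fractions from LAI change
#'
#' Splits the canopy into new / growing / mature / senescent leaf fractions
#' from the current and previous LAI, the interval length, and the mean air
#' temperature of the preceding interval. Equal LAI yields the canonical
#' 0/0.1/0.8/0.1 composition; declining LAI moves canopy into the senescent
#' class; increasing LAI grows the new/growing classes on the bud-break
#' timescales `ti` (onset of emission) and `tm = 2.3 ti` (peak emission),
#' with `ti = 5 + 0.7 (300 - Tt)` for `Tt <= 303` K and 2.9 above.
#'
#' @param lai_c,lai_p Current and previous-interval LAI.
#' @param t_days Interval length in days.
#' @param t_t Mean air temperature of the preceding interval (K).
#' @return Named vector `(f_new, f_gro, f_mat, f_sen)` summing to 1.
#' @export
leaf_age_fractions <- function(lai_c, lai_p, t_days, t_t) {
  if (lai_c < 0 || lai_p < 0) stop("LAI must be non-negative")
  if (t_days <= 0) stop("interval must be positive")
  if (lai_c == lai_p) {
    return(c(f_new = 0, f_gro = 0.1, f_mat = 0.8, f_sen = 0.1))
  }
  if (lai_c < lai_p) {
    return(c(f_new = 0, f_gro = 0,
             f_mat = lai_c / lai_p, f_sen = (lai_p - lai_c) / lai_p))
  }
  ti <- bud_break_ti(t_t)
  tm <- 2.3 * ti
  r <- lai_p / lai_c
  f_new <- if (t_days <= ti) 1 - r else (ti / t_days) * (1 - r)
  f_mat <- if (t_days <= tm) r else r + ((t_days - tm) / t_days) * (1 - r)
  f_gro <- max(1 - f_new - f_mat, 0)
  c(f_new = f_new, f_gro = f_gro, f_mat = f_mat, f_sen = 0)
}

#' Days between bud break and emission onset
#'
#' @param t_t Mean air temperature of the preceding interval (K).
#' @return `ti` in days.
#' @export
bud_break_ti <- function(t_t) {
  ifelse(t_t <= 303, 5 + 0.7 * (300 - t_t), 2.9)
}

#' Leaf-age activity factor for evergreen conifers
#'
#' Evergreen needleleaf canopies keep their leaves year-round, so their
#' leaf-age factor is fixed at 1 in every season.
#'
#' @return 1.
#' @export
evergreen_gamma_a <- function() 1

#' Leaf-age fraction series from a daily LAI series
#'
#' Steps through daily LAI at a fixed interval (default 8 days, a typical
#' satellite revisit composite), computing the leaf-age fractions of each
#' interval from the LAI at its endpoints and the mean temperature of the
#' preceding interval.
#'
#' @param lai_daily Daily LAI values (length = number of days).
#' @param temp_daily Daily mean air temperature (K), same length.
#' @param step_days Interval length in days.
#' @return Data frame with `day` (interval start), `f_new`, `f_gro`,
#'   `f_mat`, `f_sen`; fractions hold piecewise-constant from `day`.
#' @export
leaf_age_series <- function(lai_daily, temp_daily, step_days = 8) {
  nd <- length(lai_daily)
  stopifnot(length(temp_daily) == nd)
  starts <- seq(1, nd, by = step_days)
  out <- matrix(NA_real_, nrow = length(starts), ncol = 4)
  for (k in seq_along(starts)) {
    s <- starts[k]
    lai_c <- lai_daily[s]
    lai_p <- lai_daily[max(s - step_days, 1)]
    tt <- mean(temp_daily[max(s - step_days, 1):max(s - 1, 1)])
    out[k, ] <- leaf_age_fractions(lai_c, lai_p, step_days, tt)
  }
  data.frame(day = starts, f_new = out[, 1], f_gro = out[, 2],
             f_mat = out[, 3], f_sen = out[, 4])
}
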