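# Aggregation and comparison layer: diurnal-period / season / aspect / PFT
# classification, seasonal and per-species summaries, and the
# Kruskal-Wallis + Dunn post-hoc machinery with a compact letter display.

#' Classify hours into diurnal periods
#'
#' Morning 08:00-10:00, afternoon 14:00-16:00, evening 20:00-22:00
#' (inclusive of the named hours), everything else `"other"`.
#'
#' @param hour Integer hour of day in `[0, 24)`.
#' @return Character vector of period labels.
#' @export
classify_day_period <- function(hour) {
  if (any(hour < 0 | hour >= 24)) stop("hour must lie in [0, 24)")
  out <- rep("other", length(hour))
  out[hour >= 8 & hour <= 10] <- "morning"
  out[hour >= 14 & hour <= 16] <- "afternoon"
  out[hour >= 20 & hour <= 22] <- "evening"
  out
}

#' Classify dates into meteorological seasons
#'
#' March-May spring, June-August summer, September-November autumn,
#' December-February winter.
#'
#' @param date `Date`/`POSIXct` vector (or integer months).
#' @return Character vector of season labels.
#' @export
classify_season <- function(date) {
  m <- if (is.numeric(date)) date else as.POSIXlt(date)$mon + 1
  out <- rep("winter", length(m))
  out[m %in% 3:5] <- "spring"
  out[m %in% 6:8] <- "summer"
  out[m %in% 9:11] <- "autumn"
  out
}

#' Classify pixels into aspect groups
#'
#' 90-degree bins centred on the cardinal directions (N `[315, 45)`,
#' E `[45, 135)`, S `[135, 225)`, W `[225, 315)`); pixels flatter than the
#' slope threshold are `"flat"`.
#'
#' @param aspect_deg Aspect in degrees clockwise from north, `[0, 360)`.
#' @param slope_deg Slope in degrees.
#' @param flat_below Slope threshold (degrees) below which a pixel is flat.
#' @return Character vector among `"N"`, `"E"`, `"S"`, `"W"`, `"flat"`.
#' @export
classify_aspect <- function(aspect_deg, slope_deg, flat_below = 5) {
  a <- aspect_deg %% 360
  out <- rep("N", length(a))
  out[a >= 45 & a < 135] <- "E"
  out[a >= 135 & a < 225] <- "S"
  out[a >= 225 & a < 315] <- "W"
  out[slope_deg < flat_below] <- "flat"
  out
}

#' Seasonal summary of compound-class emission rates
#'
#' For an `emission_run`, summarises the per-season mean and standard
#' deviation of the monoterpene and sesquiterpene class totals over forest
#' pixel-hours; a precomputed class-mean table (columns `season`,
#' `compound_class`, `mean`, optionally `sd`) is accepted directly. From
#' either source the per-season class proportions and each class's
#' max/min seasonal ratio are derived.
#'
#' @param x An `emission_run` or a seasonal class-mean data frame.
#' @return List with `table` (season x class means), `proportions` (percent
#'   of the terpene total within each season) and `ratio` (per-class
#'   max/min seasonal ratio; `NA` with a warning if only one season is
#'   present).
#' @export
seasonal_summary <- function(x) {
  tab <- if (inherits(x, "emission_run")) {
    x$class_season_stats
  } else {
    stopifnot(all(c("season", "compound_class", "mean") %in% names(x)))
    as.data.frame(x)
  }
  classes <- unique(tab$compound_class)
  seasons <- unique(tab$season)
  wide <- sapply(classes, function(cl) {
    v <- tab$mean[tab$compound_class == cl][match(seasons, tab$season[tab$compound_class == cl])]
    v
  })
  wide <- matrix(wide, nrow = length(seasons),
                 dimnames = list(seasons, classes))
  prop <- 100 * wide / rowSums(wide)
  ratio <- apply(wide, 2, function(v) {
    if (length(v) < 2 || any(!is.finite(v)) || min(v) <= 0) NA_real_
    else max(v) / min(v)
  })
  if (length(seasons) < 2) {
    warning("fewer than two seasons present; max/min ratio undefined")
  }
  list(table = tab, means = wide, proportions = prop, ratio = ratio)
}

#' Annual per-species emission rates and terpene proportions
#'
#' Mean flux of each species over forest pixels for the run period, with
#' each species' percentage of the terpene total; species are ordered by
#' class and then by rate.
#'
#' @param run An `emission_run`.
#' @return Data frame with `compound_class`, `compound`, `mean_rate`,
#'   `proportion` (percent).
#' @export
compound_proportions <- function(run) {
  fr <- run$forest
  rate <- colMeans(run$pixel_mean[fr, , drop = FALSE])
  out <- data.frame(compound_class = run$compounds$compound_class,
                    compound = run$compounds$compound,
                    mean_rate = as.numeric(rate), row.names = NULL)
  terp <- out$compound_class %in% c("monoterpene", "sesquiterpene")
  out$proportion <- NA_real_
  out$proportion[terp] <- 100 * out$mean_rate[terp] / sum(out$mean_rate[terp])
  out[order(out$compound_class, -out$mean_rate), ]
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Rank-based one-way comparison of two or more groups: the tie-corrected
#' Kruskal-Wallis H statistic, Dunn's pairwise z-tests with a
#' multiple-comparison adjustment (Holm by default), and a compact letter
#' display in which groups sharing a letter are not significantly
#' different.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (coerced to factor).
#' @param alpha Significance level for the letter display.
#' @param adjust Adjustment method passed to [stats::p.adjust()].
#' @return List with `h`, `df`, `p_value`, `pairwise` (data frame of group
#'   pairs, z, raw and adjusted p) and `letters` (named character vector).
#' @export
rank_test <- function(values, groups, alpha = 0.05, adjust = "holm") {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least two non-empty groups")
  if (length(unique(values)) == 1) {
    lev <- levels(g)
    pw <- if (nlevels(g) > 1) {
      cmb <- combn(lev, 2)
      data.frame(group1 = cmb[1, ], group2 = cmb[2, ], z = 0, p = 1, p_adj = 1)
    } else NULL
    return(list(h = 0, df = nlevels(g) - 1, p_value = 1, pairwise = pw,
                letters = setNames(rep("a", length(lev)), lev)))
  }
  kw <- kruskal.test(values, g)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  lev <- levels(g)
  cmb <- combn(lev, 2)
  z <- apply(cmb, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(s2 * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  p_adj <- p.adjust(p, method = adjust)
  pw <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                   z = as.numeric(z), p = as.numeric(p),
                   p_adj = as.numeric(p_adj), row.names = NULL)
  letters <- cld_letters(lev[order(rbar[lev])], pw, alpha)
  list(h = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, pairwise = pw, letters = letters)
}

# compact letter display by the sweep method: groups ordered by mean rank;
# each maximal run of mutually non-significant groups shares a letter
cld_letters <- function(ordered_groups, pairwise, alpha) {
  k <- length(ordered_groups)
  sig <- function(a, b) {
    i <- (pairwise$group1 == a & pairwise$group2 == b) |
      (pairwise$group1 == b & pairwise$group2 == a)
    any(pairwise$p_adj[i] < alpha)
  }
  # maximal end index of a mutually non-significant run starting at i
  jmax <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k) {
      ok <- TRUE
      for (m in i:j) {
        if (sig(ordered_groups[m], ordered_groups[j + 1])) { ok <- FALSE; break }
      }
      if (!ok) break
      j <- j + 1
    }
    jmax[i] <- j
  }
  # keep only runs not contained in an earlier (longer) run
  starts <- which(c(TRUE, diff(jmax) > 0))
  runs <- lapply(starts, function(i) i:jmax[i])
  out <- setNames(rep("", k), ordered_groups)
  for (ri in seq_along(runs)) {
    lab <- letters[ri]
    for (ix in runs[[ri]]) out[ix] <- paste0(out[ix], lab)
  }
  out
}

#' Grouped comparison of pixel-level emission rates
#'
#' Compares time-aggregated per-pixel terpene emission rates between groups
#' (slope aspect, PFT, season or diurnal period), using one value per pixel
#' per group as the statistical unit to avoid pseudo-replication across
#' hours.
#'
#' @param run An `emission_run`.
#' @param by One of `"aspect"`, `"pft"`, `"season"`, `"day_period"`.
#' @param terrain [terrain_model()] (required for `by = "aspect"`).
#' @param flat_below Slope threshold (degrees) for the flat class.
#' @return List with `summary` (per-group n, mean, sd) and `test`
#'   ([rank_test()] output).
#' @export
compare_groups <- function(run, by = c("aspect", "pft", "season", "day_period"),
                           terrain = NULL, flat_below = 5) {
  by <- match.arg(by)
  fr <- run$forest
  terp_pix <- rowSums(run$pixel_mean[, run$compounds$compound_class %in%
                                       c("monoterpene", "sesquiterpene"),
                                     drop = FALSE])
  if (by == "aspect") {
    if (is.null(terrain)) stop("terrain model required for aspect grouping")
    grp <- classify_aspect(as.vector(terrain$aspect) * 180 / pi,
                           as.vector(terrain$slope) * 180 / pi,
                           flat_below = flat_below)
    values <- terp_pix[fr]
    groups <- grp[fr]
  } else if (by == "pft") {
    values <- terp_pix[fr]
    groups <- run$pft[fr]
  } else if (by == "season") {
    m <- run$pixel_season_class[fr, , 1] + run$pixel_season_class[fr, , 2]
    values <- as.vector(m)
    groups <- rep(colnames(run$pixel_season_class), each = sum(fr))
  } else {
    m <- run$pixel_period_class[fr, , 1] + run$pixel_period_class[fr, , 2]
    values <- as.vector(m)
    groups <- rep(colnames(run$pixel_period_class), each = sum(fr))
  }
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  smry <- aggregate(values, list(group = groups),
                    function(v) c(n = length(v), mean = mean(v), sd = sd(v)))
  smry <- data.frame(group = smry$group, n = smry$x[, "n"],
                     mean = smry$x[, "mean"], sd = smry$x[, "sd"])
  list(summary = smry, test = rank_test(values, groups))
}
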