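# MEGAN constants: compound parameter table, standard-condition emission
# rates per PFT, the standard-condition definition, and soil/CO2 parameters.
# These tables are the single source of truth for every symbol used by the
# activity-factor and emission modules.

PFT_LEVELS <- c("needleleaf_conifer", "broadleaf_deciduous", "mixed", "nonforest")
COMPOUND_CLASSES <- c("isoprene", "monoterpene", "sesquiterpene", "other_voc")

# Map typographic variants (Greek letters, unicode dashes) onto the ascii
# names used in the built-in tables so lookups accept either spelling.
normalize_compound <- function(x) {
  x <- gsub("α", "a", x)
  x <- gsub("β", "b", x)
  x <- gsub("−|–", "-", x)
  trimws(x)
}

#' Load the per-compound MEGAN parameter table
#'
#' Returns the 19-species table of emission-model parameters: temperature
#' sensitivity `beta` (1/K), light-dependent fraction `ldf`, the empirical
#' temperature-response coefficients `ct1` and `ceo`, and the four leaf-age
#' class coefficients `a_new`, `a_gro`, `a_mat`, `a_old`.
#'
#' @param source Optional path to a CSV with the same columns as the built-in
#'   table (`compound_class, compound, beta, ldf, ct1, ceo, a_new, a_gro,
#'   a_mat, a_old`). When `NULL` the packaged defaults are used.
#' @return A `data.frame` with one row per compound species.
#' @export
load_compound_params <- function(source = NULL) {
  path <- if (is.null(source)) {
    system.file("extdata", "megan_compound_params.csv", package = "terpflux",
                mustWork = TRUE)
  } else source
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound_class", "compound", "beta", "ldf", "ct1", "ceo",
                "a_new", "a_gro", "a_mat", "a_old")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("compound parameter file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$compound <- normalize_compound(tab$compound)
  num <- setdiff(required, c("compound_class", "compound"))
  tab[num] <- lapply(tab[num], as.numeric)
  bad <- which(!(tab$ldf >= 0 & tab$ldf <= 1) | tab$beta <= 0 |
                 tab$ct1 <= 0 | tab$ceo <= 0 |
                 tab$a_new <= 0 | tab$a_gro <= 0 | tab$a_mat <= 0 |
                 tab$a_old <= 0 | !(tab$compound_class %in% COMPOUND_CLASSES))
  if (length(bad) > 0) {
    stop("invalid compound parameter row(s): ",
         paste(tab$compound[bad], collapse = ", "))
  }
  class(tab) <- c("compound_params", "data.frame")
  tab
}

#' Look up the parameters of one compound species
#'
#' @param params Table from [load_compound_params()].
#' @param compound Species name (Greek-letter spellings accepted).
#' @return A one-row list of parameters.
#' @export
compound_spec <- function(params, compound) {
  key <- normalize_compound(compound)
  i <- match(key, params$compound)
  if (is.na(i)) stop("unknown compound species: ", compound)
  as.list(params[i, ])
}

#' Load the standard-condition emission-rate table
#'
#' Standard-condition emission rates epsilon (ug m-2 h-1) for each compound
#' species under the two temperate forest PFTs (needleleaf conifer,
#' broadleaf deciduous).
#'
#' @inheritParams load_compound_params
#' @return A `data.frame` with columns `compound_class`, `compound`,
#'   `needleleaf_conifer`, `broadleaf_deciduous`.
#' @export
load_emission_table <- function(source = NULL) {
  path <- if (is.null(source)) {
    system.file("extdata", "megan_emission_rates.csv", package = "terpflux",
                mustWork = TRUE)
  } else source
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("compound_class", "compound", "needleleaf_conifer",
                "broadleaf_deciduous")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("emission-rate file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$compound <- normalize_compound(tab$compound)
  tab$needleleaf_conifer <- as.numeric(tab$needleleaf_conifer)
  tab$broadleaf_deciduous <- as.numeric(tab$broadleaf_deciduous)
  if (any(is.na(tab$needleleaf_conifer)) || any(is.na(tab$broadleaf_deciduous))) {
    stop("emission-rate table has missing (species, PFT) entries")
  }
  if (any(tab$needleleaf_conifer < 0) || any(tab$broadleaf_deciduous < 0)) {
    stop("negative standard-condition emission rate")
  }
  class(tab) <- c("emission_table", "data.frame")
  tab
}

#' Standard-condition emission rate of one (species, PFT) pair
#'
#' @param table Table from [load_emission_table()].
#' @param compound Species name.
#' @param pft `"needleleaf_conifer"` or `"broadleaf_deciduous"`.
#' @return Emission rate in ug m-2 h-1.
#' @export
epsilon <- function(table, compound, pft) {
  pft <- match.arg(pft, c("needleleaf_conifer", "broadleaf_deciduous"))
  key <- normalize_compound(compound)
  i <- match(key, table$compound)
  if (is.na(i)) stop("compound species absent from emission table: ", compound)
  table[[pft]][i]
}

#' Terpene subset of a parameter or emission table
#'
#' Restricts a table to the monoterpene and sesquiterpene rows (the
#' human-beneficial terpenes), including the two "Others" aggregate
#' pseudo-species.
#'
#' @param tab A table from [load_compound_params()] or [load_emission_table()].
#' @return The terpene rows, in table order.
#' @export
terpene_subset <- function(tab) {
  tab[tab$compound_class %in% c("monoterpene", "sesquiterpene"), , drop = FALSE]
}

#' Names of the terpene species modelled
#' @param params Optional compound table; defaults to the built-in one.
#' @return Character vector of terpene species names.
#' @export
terpene_species <- function(params = load_compound_params()) {
  terpene_subset(params)$compound
}

#' MEGAN standard conditions
#'
#' The reference state at which every activity factor normalises to 1:
#' effective LAI 5, leaf-age composition 0/0.1/0.8/0.1
#' (new/growing/mature/old), instantaneous air temperature 303 K, 24 h/240 h
#' average temperature 297 K, 24 h/240 h average PPFD 200 umol m-2 s-1
#' (sun leaves; 50 for shade), solar angle 60 degrees, transmittance 0.6.
#' The instantaneous standard PPFD is not tabulated by the model description;
#' it is fixed at 1500 umol m-2 s-1, consistent with a 60-degree solar angle
#' and 0.6 atmospheric transmittance; any residual departure of the factors
#' from 1 is absorbed by the canopy environment coefficient calibration.
#'
#' @return A named list of standard-condition values.
#' @export
standard_conditions <- function() {
  list(
    lai_v = 5,
    leaf_age_fractions = c(f_new = 0.0, f_gro = 0.1, f_mat = 0.8, f_sen = 0.1),
    t_inst = 303,
    t_avg = 297,
    p_avg_sun = 200,
    p_avg_shade = 50,
    p_inst = 1500,
    solar_angle_deg = 60,
    transmittance = 0.6
  )
}

#' Soil-moisture and CO2 response parameters (isoprene only)
#'
#' Defaults are calibrated so that the CO2 factor equals 1 at the reference
#' ambient CO2 level (400 ppm, internal concentration 0.7 x ambient); all
#' values are overridable.
#'
#' @param theta_w Wilting point (m3 m-3).
#' @param delta_theta1 Width of the soil-moisture ramp (m3 m-3).
#' @param is_max,c_star,h Empirical CO2-response coefficients.
#' @param ci_fraction Internal/ambient CO2 ratio.
#' @param co2_ref Reference ambient CO2 (ppm) at which the factor is 1.
#' @return Named list of parameters.
#' @export
soil_co2_params <- function(theta_w = 0.1, delta_theta1 = 0.06,
                            is_max = NULL, c_star = 585, h = 1.4614,
                            ci_fraction = 0.7, co2_ref = 400) {
  if (theta_w < 0 || theta_w > 0.5) stop("theta_w must lie in [0, 0.5]")
  if (delta_theta1 <= 0) stop("delta_theta1 must be positive")
  if (is.null(is_max)) {
    # anchor the CO2 factor at exactly 1 for the reference ambient level
    ci <- ci_fraction * co2_ref
    is_max <- (c_star^h + ci^h) / c_star^h
  }
  list(theta_w = theta_w, delta_theta1 = delta_theta1, is_max = is_max,
       c_star = c_star, h = h, ci_fraction = ci_fraction, co2_ref = co2_ref)
}

#' Write parameter tables back to CSV
#'
#' Mirrors the input schema column-for-column so a written file reloads
#' bit-identically.
#'
#' @param tab Table from [load_compound_params()] or [load_emission_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_param_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
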