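---
title: "Modelling hourly terpene emission from temperate forest landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hourly terpene emission from temperate forest landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terpflux)
```

## The problem

Monoterpenes (C10) and sesquiterpenes (C15) emitted by forest canopies are
the compounds most often credited with the physiological benefits of
"forest bathing". Managing a recreational forest for those benefits needs
to know *when* and *where* the canopy emits most, which is a modelling
problem: emission depends jointly on light, temperature, canopy leaf area
and leaf age, and on the tree functional types present. `terpflux`
implements the MEGAN v2.1 canopy emission formulation at a 30 m grid and
hourly step, plus everything needed to drive it from station weather, a
DEM and an NDVI time series, or from a fully synthetic landscape.

## The model

The hourly areal emission rate of compound $i$ over a pixel containing
plant functional types (PFTs) $j$ with cover fractions $\chi_j$ is

$$F_i = \gamma_i \sum_j \varepsilon_{i,j}\,\chi_j
  \qquad [\mu g\, m^{-2}\, h^{-1}]$$

where $\varepsilon_{i,j}$ is the standard-condition emission rate of the
(species, PFT) pair and $\gamma_i$ the dimensionless emission activity
factor

$$\gamma_i = C_{CE}\; LAI_v\; \gamma_{P,i}\, \gamma_{T,i}\, \gamma_{A,i}\,
  \gamma_{SM,i}\, \gamma_{C,i}.$$

The built-in tables (`load_emission_table()`, `load_compound_params()`)
cover 19 compound species — isoprene, 8 monoterpene rows, 3 sesquiterpene
rows (each class including an "Others" aggregate treated as a single
pseudo-species) and 7 other VOCs — for the temperate needleleaf-conifer
and broadleaf-deciduous PFT pair. Mixed forest is not a third parameter
column: a mixed pixel is modelled as two half-weight sub-canopies,
$\chi = (0.5, 0.5)$, the conifer half with the evergreen leaf-age rule and
the deciduous half with the phenological one.

**Standard conditions** are $LAI_v = 5$, leaf-age composition
0/0.1/0.8/0.1 (new/growing/mature/old), instantaneous temperature 303 K,
trailing 24 h/240 h temperature 297 K and PPFD 200 µmol m⁻² s⁻¹. The
activity factor must be exactly 1 there; because the published factor
formulas do not evaluate to exactly 1 at those drivers, $C_{CE}$ is
calibrated numerically per compound rather than hard-coded
(`calibrate_cce()`). Two further choices matter:

* The instantaneous standard PPFD is not tabulated; we fix it at
  1500 µmol m⁻² s⁻¹, consistent with the standard 60° solar angle and 0.6
  atmospheric transmittance. Whatever residual it leaves in
  $\gamma_P$ is absorbed by $C_{CE}$.
* The evergreen canopy pins $\gamma_A = 1$ while a deciduous canopy at the
  standard age composition has $\gamma_A \ne 1$ (e.g. 1.085 for
  monoterpenes), so $C_{CE}$ is calibrated **per PFT leaf-age mode** as
  well. This is what makes a pure-conifer pixel at standard conditions
  emit each species at exactly its tabulated rate.

### Light response

$\gamma_P = (1 - LDF) + LDF\,\gamma_{PLDF}$ with
$\gamma_{PLDF} = C_p\,\alpha\,P/\sqrt{1 + (\alpha P)^2}$,
$\alpha = 0.004 - 0.0005\ln P_{240}$ and
$C_p = 0.0468\,P_{240}^{0.6} e^{0.0005 (P_{24} - 200)}$. Two published
typesetting slips are corrected here: the $\alpha$ coefficient is 0.0005
(the printed 0.005 gives negative $\alpha$ — hence negative emission — at
the standard $P_{240} = 200$), and the denominator carries the square
root, following the MEGAN v2.1 source formulation. With no light history
($P_{240} = 0$) the light-dependent share is zero and a warning is
raised.

### Temperature response

$\gamma_T = (1 - LDF)\,\gamma_{TLIF} + LDF\,\gamma_{TLDF}$. The
light-independent part is $e^{\beta (T - 303)}$. The light-dependent part
is an optimum curve whose optimum temperature
$T_{opt} = 313 + 0.6\,(T_{240} - 297)$ and height
$E_{opt} = C_{eo} e^{0.05 (T_{24} + T_{240} - 2 \cdot 297)}$ shift with
the trailing temperature history. The published description uses one
symbol for the standard temperature in both places; only the reading
"297 K inside $E_{opt}$/$T_{opt}$, 303 K in the instantaneous response"
makes $\gamma_T \approx 1$ at standard conditions, which the unity clause
requires, so that is what is implemented. The `1/0.0083` constant is kept
as printed (the MEGAN source uses 0.00831; the difference is < 0.2 %).

### Leaf age

Deciduous canopies are split into new/growing/mature/senescent fractions
from LAI change (`leaf_age_fractions()`): equal LAI gives the canonical
0/0.1/0.8/0.1; declining LAI moves canopy into the senescent class;
increasing LAI grows the young classes on the bud-break timescales
$t_i = 5 + 0.7(300 - T_t)$ for $T_t \le 303$ K (2.9 above — note the rule
is continuous at the 303 K pivot) and $t_m = 2.3\,t_i$. The interval
length is the LAI database revisit; we step the smoothed daily LAI at 8
days (a typical satellite composite period), with $T_t$ the mean air
temperature of the preceding interval. Evergreen conifer canopies use
$\gamma_A = 1$ year-round.

Soil moisture and CO2 affect isoprene only; both factors default to 1 (as
they are for every terpene) and the isoprene paths
(`gamma_sm_isoprene()`, `gamma_c_isoprene()`) are off unless drivers are
supplied. The CO2 parameters are anchored so the factor is exactly 1 at
400 ppm ambient.

## Drivers

Hourly pyranometer radiation (MJ m⁻² h⁻¹) becomes PPFD via
277.78 (to W m⁻²) × 2.02 µmol W⁻¹ s⁻¹. Trailing 24 h/240 h means use an
expanding window during the first 240 h (flagged as warm-up in the run
metadata); leaf temperature is taken equal to measured air temperature,
as the driving station measures both with one sensor.

The topographic correction multiplies horizontal PPFD by
$\max(0, \cos\theta_i)/\cos\theta_z$ — the cosine of the sun/surface
angle over the cosine of the solar zenith — per pixel, from Horn
slope/aspect on the DEM and a standard low-precision solar ephemeris
(Spencer series; ~0.2° accuracy, ample here). The ratio is capped at 3
and floored at 0: near sunrise/sunset the denominator vanishes while
measured horizontal radiation is already near zero, so the cap only
guards numerics. Cast shadows and horizon obstruction are deliberately
not modelled. The per-pixel 24 h/240 h light history is computed from the
*corrected* series (correcting only the instantaneous PPFD was the
alternative; correcting before averaging keeps the history consistent
with what the pixel actually received).

## Phenology from NDVI

NDVI = $(\rho_{NIR} - \rho_{red})/(\rho_{NIR} + \rho_{red})$ is converted
to LAI with the Korean-forest regression $LAI = 6.7537\,NDVI + 0.8384$
(floored at 0). The raw series is repaired with a Hampel filter (rolling
median ± `nsigma` × 1.4826 × MAD; defaults half-window 3 samples,
`nsigma` 3, both configurable), which is also what removes
monsoon-depressed values — no separate cloud mask. The series is
reflect-padded so the first/last window-width points are screened too.
The repaired LAI series is then smoothed with a double logistic

$$f(t) = mn + (mx - mn)\left[\frac{1}{1 + e^{-rsp (t - sos)}} +
  \frac{1}{1 + e^{rsw (t - eos)}} - 1\right]$$

fitted by Levenberg–Marquardt with starts from the 5th/95th percentiles
and half-amplitude crossings and box bounds keeping $sos < eos$.
Degenerate series (seasonal amplitude < 0.05 LAI) and non-convergent fits
fall back to linear interpolation with a warning — this is the expected
path for flat conifer series, not an error. Vegetation cover fraction is
taken as 1 for forest pixels at 30 m (closed canopy), so $LAI_v = LAI$;
non-forest pixels emit zero and are excluded from statistics.

## The synthetic landscape

`synthetic_scenario()` defines a seeded, fully reproducible stand-in for
the study conditions: a 50×50 grid of 30 m cells at 37.5° N; temperature
as annual (mean 284.5 K, amplitude 12 K, peak in early August) plus
diurnal (4 K, peak 15:00) sinusoids with AR(1) noise; radiation as the
clear-sky geometric curve damped by a daily cloud factor whose mean drops
from 0.72 to 0.42 inside the monsoon window (days 172–225); a DEM of six
random Gaussian hills; a region-grown PFT mosaic hitting 61.7 %
deciduous / 31.0 % conifer / 6.4 % mixed among forest pixels with the
valley floor as non-forest; and NDVI truth curves per PFT
(double-logistic for deciduous, a high mildly-seasonal plateau for
conifer) with Gaussian noise (σ = 0.03) and downward outliers of depth
0.3–0.7 — optically thick cloud depresses NDVI strongly — at rate 0.15
per observation inside the monsoon window and 0.033 outside. Truth
parameters and injected outlier positions are returned so recovery is
testable. The monsoon exists only through the cloud factor and the NDVI
outliers; the model never consumes precipitation, so none is generated.

What the generator does **not** emulate: Sentinel-2 radiometry, orbit
gaps and real cloud masks; spatially correlated weather; interannual
variability; species mixtures beyond the two-PFT table. Passing the
end-to-end tests therefore shows the pipeline is internally consistent
under realistic structure, not that it reproduces any particular site's
absolute fluxes.

## Aggregation and comparison statistics

Diurnal periods are morning 08–10 h, afternoon 14–16 h, evening 20–22 h;
seasons are meteorological (MAM/JJA/SON/DJF). Aspect classes are 90°
bins centred on the cardinal directions with a 5° slope threshold for
"flat" (both bin edges and threshold are conventions, configurable).
Group comparisons use the Kruskal–Wallis test with tie correction and
Dunn's pairwise z-tests; the statistical unit is the pixel-level
time-aggregated mean (one value per pixel per group) to avoid
pseudo-replication across hours. The pairwise adjustment is Holm
(configurable), summarised as a compact letter display in which groups
sharing a letter do not differ significantly.

`seasonal_summary()` also accepts a precomputed season × class mean table
and derives per-season class proportions and each class's max/min
seasonal ratio from it, so published summary tables can be re-analysed
directly.

## Numerical choices and degenerate inputs

* Rolling means: expanding during warm-up; first 240 h flagged.
* Incidence ratio: cap 3, denominator floor 10⁻³, zenith ≥ 90° → 0.
* Leaf-age closure: fractions are clamped against ~10⁻17 float dust so
  they always sum to 1 and stay non-negative.
* `gamma_p` clamps its result at 0 ($\alpha$ can go negative for
  $P_{240} > e^8$ µmol m⁻² s⁻¹).
* Ties in `rank_test` use the standard tie-corrected variance; an
  all-identical sample short-circuits to $p = 1$ with a shared letter.
* Chunked grid evaluation bounds memory; chunk size has no effect on
  values (asserted in the tests).

## Problem sizes used by the test-suite

Unit tests run on 1–16 pixel grids and short weather windows; the
property sweeps use 10⁴ random draws and 1000 null replicates for the
rank-test calibration; the end-to-end check runs the full default
scenario — a 50×50 grid over a complete hourly year, about 2 minutes of
compute — and checks phenology-truth recovery (noiseless parameter
recovery within 1 %, daily LAI RMSE below the observation noise, ≥ 90 %
of injected NDVI outliers repaired) and the directional orderings
(summer > winter per pixel, conifer > mixed > deciduous, south ≥ north,
sesquiterpene share larger in summer than winter — the β = 0.17 vs 0.10
temperature sensitivities make the sesquiterpene/monoterpene ratio rise
with temperature).

## Known limitations

Outputs are *source fluxes*, not ambient concentrations: no transport,
mixing, deposition or chemistry is modelled, so therapeutic exposure
cannot be read off the maps directly. The canopy is a single big leaf
per pixel (no sun/shade partitioning or within-canopy extinction beyond
the $C_{CE}$ normalisation). Weather is spatially uniform apart from the
topographic light factor. Agricultural and other non-forest vegetation is
assumed non-emitting. Raster I/O is plain-text (ESRI ASCII grid) and
tabular CSV; there is no geodesy beyond a common grid.
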