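---
title: "Refining a light-use-efficiency carbon-flux model with SIF and soil observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining a light-use-efficiency carbon-flux model with SIF and soil observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vprmsif)
```

## The model

VPRM estimates gross primary productivity per grid cell and 8-day composite
period as

$$GPP = |\lambda| \; P_{scale} \, T_{scale} \, W_{scale} \; EVI \cdot
SWdown \, \frac{1}{1 + SWdown/SWdown_0},$$

and ecosystem respiration as the clamped linear response
$R_{eco} = \alpha \max(T_{air}, T_{thresh}) + \beta$, with one parameter
vector $(\lambda, SWdown_0, \alpha, \beta)$ per vegetation class. Two
calibrations ship with the package (`vprm_param_table()`): a tropical set
and a European set. The European set prints $\lambda$ with the
uptake-negative sign convention; GPP is always computed with $|\lambda|$
and reported as a positive uptake magnitude, so the choice of set changes
only magnitudes, never signs.

The dimensionless scalars:

* $T_{scale}$ follows the quadratic-ratio temperature response with
  $T_{min}/T_{opt}/T_{max} = 0/20/45$ °C by default for all classes.
  Photosynthesis is treated as absent at or outside the limits; values
  exactly at $T_{min}$ or $T_{max}$ resolve to 0 (the "absent" branch), a
  tie-break that only matters on a set of measure zero.
* $P_{scale} = (1 + LSWI)/2$ during green-up, 1 for evergreen forest
  (year-round canopy), 1 at the time of maximum greenness, and 0 over
  `"Other"` (water/unclassified). "Maximum greenness" is not observable
  directly, so we flag, per cell, the composites whose EVI reaches at least
  99 % of the cell's annual maximum (`max_greenness_mask()`, fraction
  configurable). A strict `== max` test would be fragile under floating
  noise and would flag exactly one composite even on plateaus.
* $W_{scale} = (1 + LSWI)/(1 + LSWI_{max})$, with $LSWI_{max}$ the
  per-cell maximum over the calendar year. A "growing season" window would
  need phenological bounds we do not model; over regions with a full annual
  cycle the calendar-year maximum coincides with the growing-season one.

EVI and LSWI use the standard MODIS-style formulations
($2.5(N-R)/(N+6R-7.5B+1)$ and $(N-S)/(N+S)$), and the fraction of radiation
absorbed by the photosynthetically active vegetation is taken equal to EVI
with no offset variant. $T_{thresh}$ defaults to 0 °C for every class and
is configurable through `temperature_limits()`.

## Grids, compositing, missing data

Cells are center-registered with half-open $[c - r/2, c + r/2)$ extents,
which makes the 0.05° SIF grid nest exactly inside the 0.1° model grid.
`regrid_block_mean()` averages the non-missing fine cells of each coarse
cell (the estimator is unweighted block mean; cell-area weighting over a
0.1° block changes means by well under the data noise), and refuses
non-nesting grids rather than resampling. The composite calendar restarts
at day-of-year 1 each year: 46 periods, the last truncated to 5–6 days.
Missing data travel as `NA` masks, never as sentinel values: a composite or
coarse cell is missing exactly when no contributing datum exists.

## SIF harmonization

The two SIF products differ by a roughly multiplicative, biome-dependent
radiometric offset. `fit_sif_scaling()` estimates the per-class factor $S$
in $TROPOSIF = S \cdot GOSIF$ as the **ratio of per-class sums** over
matched 8-day pairs. This estimator is exactly invariant to common
rescaling of both products, reproduces a pure multiplicative offset
exactly, and makes the per-class sums of the scaled product match by
construction. A least-squares slope-through-origin variant
(`estimator = "slope0"`) is available; on proportional data the two agree.
The paired $R^2$ is the squared Pearson correlation of the matched 8-day
pairs.

## SIF to GPP, and transferring coefficients

`gpp_from_sif()` applies the per-biome linear map $GPP = \gamma \, SIF + C$
and floors the result at zero: SIF noise can drive the line negative and
GPP is a magnitude. `transfer_coeffs()` derives TROPOSIF-side coefficients
from GOSIF-side ones by dividing **both** $\gamma$ and $C$ by the class
factor $S$ — this is the published transfer scheme, and the packaged
TROPOSIF-side table equals the transferred GOSIF-side table to the printed
two decimals.

One property of this scheme deserves emphasis. With
$TROPOSIF = S \cdot GOSIF$ exactly, the TROPOSIF route yields
$\gamma\,G + C/S$ while the GOSIF route yields $\gamma\,G + C$: the slope
part composes to the identity but the intercept inherits a $1/S$ factor, so
the two routes differ by exactly $C(1 - 1/S)$ per class (about 0.3–1.9
µmol m⁻² s⁻¹ with the packaged constants). An intercept-preserving
transfer ($C' = C$) would make the routes identical but would not reproduce
the published coefficient table; we keep the published scheme and test the
composition law as it actually holds.

## GPP refinement

`fit_eta()` calibrates the per-class affine map
$\eta \, GPP_{VPRM} + \epsilon$ onto SIF-based GPP. The default estimator
is the ratio

$$\eta = \frac{\sum GPP_{SIF} \cdot GPP_{VPRM}}{\sum GPP_{VPRM}},$$

implemented literally as published. Note its units: it is a
GPP-weighted mean of $GPP_{SIF}$ (µmol m⁻² s⁻¹), not a dimensionless
slope — the denominator may well be intended squared, but we do not guess.
The flagged alternative `estimator = "slope"` is the least-squares slope on
mean-centered pairs, i.e. the conventional dimensionless regression slope;
it recovers an exact affine relation to machine precision and is what the
recovery tests and the worked examples use. In both cases $\epsilon$ is the
mean residual, so the refined field's class mean equals the SIF-based class
mean on the fitting sample — before the non-negativity floor, which binds
only where the line goes negative. Refinement is fitted on one year of
8-day composites.

## Respiration refinement

Three experiments extend the respiration baseline
$B = \alpha \max(T_{air}, T_{thresh}) + \beta$:

| experiment | model |
|---|---|
| SM   | $\nu\,SM + \kappa B$ |
| ST   | $\tau\,ST + \kappa B$ |
| SMST | $\tau\,ST + \nu\,SM + \kappa B$ |

"Adjustment against reference fluxes" is operationalized as joint per-class
ordinary least squares with **no free intercept**: $\kappa$ scales the
whole baseline and thereby absorbs its intercept $\beta$, and the fit
minimizes squared differences to the reference. Staged single-coefficient
adjustment would be order-dependent and never beats the joint fit in RMSE.
Least-squares nesting then guarantees, on the fitting sample,
$RMSE_{SMST} \le RMSE_{SM} \le RMSE_{baseline}$ and
$RMSE_{SMST} \le RMSE_{ST}$ — the qualitative ordering the method is built
to deliver. Units are checked per field: SM as volumetric fraction
(m³ m⁻³), ST in kelvin, $T_{air}$ in °C. Rank-deficient class designs
(e.g. a predictor collinear with the baseline) are omitted with a warning
naming the collinear columns. Predictions are floored at 0.

## Evaluation

`flux_metrics()` reports squared Pearson $R^2$ (undefined and `NA` for
zero-variance series), RMSE, and mean bias error with the model-minus-
reference sign convention, satisfying
$RMSE^2 = MBE^2 + \mathrm{Var}(model - reference)$.
`monthly_means()` aggregates 8-day composites to calendar months by
apportioning straddling composites to each month in proportion to
overlapping days; an unweighted mean would double-count boundary
composites.

## The synthetic scene generator

`generate_scene()` fabricates every input deterministically from a seed
(restoring the RNG state afterwards): per-biome sinusoidal seasonal cycles
for EVI, LSWI and SIF with class-specific phases (late-season, monsoon-like
peaks for cropland and deciduous forest), reflectance bands solved back
from the target indices so `compute_evi()`/`compute_lswi()` reproduce the
configured curves, smooth seasonal meteorology and soil fields with a
deterministic spatial texture, a fine-grid SIF product and its coarse
counterpart offset by the per-class factors $s_0$ (defaulting to the
packaged reference factors) plus additive Gaussian noise, optional random
cloud-like masking, and truth-based reference fields
($GPP_{SIF} = \eta_0\,GPP_{VPRM} + \epsilon_0$;
$R_{eco} = \tau_0 ST + \nu_0 SM + \kappa_0 B + noise$).

Generator defaults are chosen once as plausible field magnitudes: air
temperature 12–34 °C, shortwave peak 1500 µmol m⁻² s⁻¹, soil moisture
0.08–0.42 m³ m⁻³, soil temperature 286–308 K, SIF amplitudes 0.4–1.1
mW m⁻² sr⁻¹ nm⁻¹ (highest for evergreen forest), SIF noise σ = 0.05,
respiration noise σ = 0.1 µmol m⁻² s⁻¹, and respiration truth
$(\nu_0, \tau_0, \kappa_0) = (5, 0.01, 0.9)$ so each term contributes an
O(1 µmol) flux. The default 20 × 20-cell domain with 46 composites yields
roughly 2000 samples per class, the scale at which the noisy-recovery
checks are run; recovery tests at σ = 0 are exact. Tests and the
acceptance script use domains between 8 × 8 and 20 × 20 cells — small
enough to run in seconds, large enough for stable per-class fits.

What the generator does **not** emulate: radiative-transfer effects,
retrieval artefacts, spatially correlated cloud structure, drought-induced
breakdown of the SIF–GPP relationship, or inter-annual variability.
Passing recovery tests therefore demonstrate that the estimators invert
the assumed data-generating structure correctly — not that the model is
unbiased on real satellite archives.

## Packaged reference constants

The per-class tables from the published real-data calibration ship as CSVs
(`reference_tables()`): the two VPRM parameter sets, the cross-sensor
factors and paired correlations, both sides of the SIF-to-GPP
coefficients, the GPP refinement factors $\eta$ (1.2–3.7), and the
FLUXNET-adjusted respiration coefficients for all three experiments. They
are reference constants for worked examples and coefficient transfer —
reproducing them would require the multi-year satellite and flux archives,
so nothing in the test suite treats them as recovery targets.

## Known limitations

* Geographic lat/lon grids only; no projections or sinusoidal satellite
  tiles.
* The phenology scalar's maximum-greenness rule is a heuristic on the EVI
  annual cycle; with bimodal greenness (double cropping) it flags only the
  global peak's neighbourhood.
* The literal ratio estimator for $\eta$ carries GPP units and can behave
  poorly when combined with the non-negativity floor; prefer
  `estimator = "slope"` when the goal is an affine correction rather than
  fidelity to the published formula.
* Refinements are per-class constants: no per-pixel or time-varying
  calibration.
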