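# vprmsif

Satellite-driven terrestrial carbon-flux modelling with the Vegetation
Photosynthesis and Respiration Model (VPRM), refined with solar-induced
chlorophyll fluorescence (SIF) and soil observations.

## The problem

Light-use-efficiency models like VPRM estimate gross primary productivity
(GPP) and ecosystem respiration (R_eco) on regular latitude/longitude grids
from satellite vegetation indices and meteorology. Their per-biome
parameters are normally calibrated against eddy-covariance towers — which
are scarce over large parts of the tropics and subtropics. This package
implements a calibration chain that substitutes satellite SIF (a direct
proxy of photosynthetic activity) and observation-based flux products for
the missing towers:

1. **Standard VPRM.** GPP = |λ| · P·T·W · EVI · SWdown / (1 + SWdown/SWdown₀)
   and R_eco = α·Tair + β, per vegetation class, with the dimensionless
   temperature (T), phenology (P) and water-stress (W) scalars derived from
   air temperature and the Land Surface Water Index (LSWI).
2. **SIF harmonization.** Two gridded SIF products at different resolutions
   and radiometric scales (an OCO-2-derived 0.05° product and a TROPOMI
   0.1° product) are put on a common grid by block-mean regridding, and a
   per-biome multiplicative factor S (TROPOSIF = S · GOSIF) is fitted as a
   ratio of class sums over matched 8-day composites.
3. **SIF → GPP.** Per-biome linear conversion GPP = γ·SIF + C, with
   coefficient transfer between products: γ' = γ/S, C' = C/S.
4. **GPP refinement.** A per-biome affine map η·GPP_VPRM + ε calibrated
   against SIF-based GPP, with ε the mean residual so the refined field is
   class-mean-unbiased on the fitting sample.
5. **R_eco refinement.** Three regression experiments adding soil moisture
   (ν·SM), soil temperature (τ·ST) or both to the scaled baseline
   κ·(α·Tair + β), fitted per biome by ordinary least squares against
   reference respiration fluxes.
6. **Evaluation.** R² (squared Pearson), RMSE and mean bias error
   (model − reference), plus day-weighted monthly aggregation of 8-day
   composites.

Because the real satellite archives are far out of desk reach, the package
ships a deterministic synthetic-scene generator that emulates their
statistical structure (per-biome seasonal cycles, cross-sensor offsets,
additive noise, cloud-like gaps) with known truth coefficients, so every
fitting operation has a recoverable target. The per-biome parameter tables
from the published calibration (VPRM parameter sets, scaling factors S,
conversion coefficients γ/C, refinement factors η, refined respiration
coefficients ν/τ/κ) are packaged as reference constants.

## Worked example

```r
library(vprmsif)

scn <- generate_scene(scene_config(n_lat = 12, n_lon = 16, seed = 7))

# harmonize the two SIF products: regrid 0.05 deg -> 0.1 deg, fit per-class S
gosif01 <- regrid_block_mean(scn$gosif, scn$grid)
scaling <- fit_sif_scaling(scn$troposif, gosif01, scn$vegmap)

# SIF-based GPP via transferred coefficients, then refine VPRM GPP onto it
gpp_tro <- gpp_from_sif(scn$troposif, scn$vegmap,
                        transfer_coeffs(sif_gpp_coeff_table("gosif"), scaling))
fit <- fit_eta(gpp_tro, scn$gpp_vprm, scn$vegmap, estimator = "slope")
head(fit, 3)
#>             class   eta epsilon    n
#> 1        Cropland 0.691    6.28 1104
#> 2 DeciduousForest 0.757    6.06 1104
#> 3 EvergreenForest 0.514    2.65 1104

refined <- apply_refinement(scn$gpp_vprm, scn$vegmap, fit)
metrics_table(list(vprm = scn$gpp_vprm, vprm_sif = refined), gpp_tro)
#>    variant   r2 rmse      mbe    n
#> 1     vprm 0.44  6.9 -2.0e+00 7728
#> 2 vprm_sif 0.56  4.5 -3.2e-17 7728
```

The refinement roughly halves the RMSE against the SIF-based GPP
(6.9 → 4.5 µmol CO₂ m⁻² s⁻¹) and removes the mean bias by construction.
The respiration refinement works the same way:

```r
params <- vprm_param_table("tropical")
f3 <- fit_reco_params("SMST", sm = scn$sm, st = scn$st, t_air = scn$t_air,
                      reco_ref = scn$reco_ref, vegmap = scn$vegmap,
                      params = params)
r3 <- predict_reco("SMST", f3, sm = scn$sm, st = scn$st, t_air = scn$t_air,
                   vegmap = scn$vegmap, vprm_params = params)
metrics_table(list(baseline = reco_vprm(scn$t_air, scn$vegmap, params),
                   refined_smst = r3), scn$reco_ref)
#>        variant   r2  rmse      mbe    n
#> 1     baseline 0.85 3.753 -3.5e+00 8832
#> 2 refined_smst 1.00 0.095  1.0e-06 8832
```

Adding soil moisture and soil temperature drives the fitted RMSE down to the
scene's noise level (0.1 µmol CO₂ m⁻² s⁻¹) and the bias to zero.

A thin command-line front end (`inst/cli/vprmsif.R`) exposes `simulate`,
`run` and `evaluate` subcommands over CSV files.

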