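# wsci — waveform structural complexity of forest canopies

Forest structural complexity — how much 3D space a canopy occupies and how
heterogeneously it fills it — predicts biodiversity, productivity and
microclimate buffering, but measuring it globally requires more than a single
height or cover number per plot. `wsci` implements a footprint-scale
complexity pipeline for large-footprint waveform lidar (GEDI-style 25 m
footprints):

1. **Reference index.** The 3D canopy entropy of a point cloud is measured
   from kernel-density estimates of its three orthogonal 2D projections,
   evaluated on a regular 10-cm lattice of spacing *s*:

   CE₂d = −Σᵢ ρᵢ · ln(ρᵢ) · s²,  CE_XYZ = √(CE_XY² + CE_XZ² + CE_YZ²)

   with the horizontal component CE_XY and the vertical component
   CE_Z = (CE_XZ + CE_YZ)/2, all in nats. An adaptive voxel-thinning step
   makes the index comparable across lidar point densities.

2. **Waveform model.** A large-footprint waveform is simulated from a point
   cloud (Gaussian footprint illumination × Gaussian system pulse), reduced
   to 101 relative-height percentiles RH0…RH100, and gradient-boosted
   regression models predict CE_XYZ — the **Waveform Structural Complexity
   Index (WSCI)** — together with its horizontal and vertical parts from
   those RH metrics, one model per plant functional type. Hyperparameters are
   chosen by 5-fold *site-blocked* (spatial) cross-validation, accepting only
   configurations whose train/validation gap in RMSE and R² stays below 5%.

3. **Uncertainty and attribution.** Mondrian split-conformal calibration
   yields 95% prediction intervals whose width adapts to the heteroskedastic
   residual spread across the predicted range; exact double-precision
   tree-Shapley values attribute each prediction to the RH features and are
   accumulated into lower (≤ RH33), middle (RH34–RH66) and upper (> RH66)
   waveform strata.

4. **Analyses.** Grid aggregation of predictions and interval sizes, a
   PCA / principal-component-regression variance partition of WSCI against
   cover, height, PAI, FHD and biomass metrics, and complexity–height
   scaling fits (WSCI ~ ln RH98) per grid cell (OLS with slope t-tests) and
   per biome (Tukey-biweight robust regression).

A seeded synthetic forest-stand generator (`generate_stand()`) and an
RH-to-complexity table generator (`simulate_rh_table()`) provide controlled
multi-layer stands and training tables, so every stage is testable without
proprietary lidar archives.

## Worked example

```r
library(wsci)

# 1. a two-layer broadleaf stand over one 25-m footprint
stand <- generate_stand(stand_params(tree_density = 400, n_layers = 2), seed = 7)
ce <- ce_components(footprint_clip(stand, c(0, 0), 25), target_count = 2000)
ce
#> canopy entropy (nats): CE_XYZ = 11.546  [CE_XY = 6.435, CE_XZ = 6.761,
#>                                          CE_YZ = 6.795, CE_Z = 6.778]

# 2. the footprint's waveform and RH metrics
rh_profile(simulate_waveform(stand))
#> RH profile (m): rh25 = 12.12, rh50 = 17.07, rh75 = 21.87, rh98 = 31.32,
#>                 rh100 = 37.32

# 3. model WSCI from RH metrics, with conformal uncertainty
sites <- simulate_rh_sites(10, seed = 42)
tab   <- simulate_rh_table(4000, sites, seed = 43)
train <- tab[tab$site_id <= "S08", ]
cal   <- tab[tab$site_id >  "S08", ]            # held-out sites
fit <- wsci_fit(train, params = wsci_grid(100, 0.7, 0.7, 2, 0.05), seed = 7)
fit <- calibrate_mondrian(fit, cal, alpha = 0.05)
predict(fit, cal[1:3, ], interval = "conformal")
#>        fit       lwr      upr  relative
#> 1 11.02326 10.295704 11.75081 0.1320037
#> 2  9.41024  8.724873 10.09561 0.1456640
#> 3 11.24986 10.629652 11.87006 0.1102600
empirical_coverage(fit, simulate_rh_table(1000, sites[9:10, ], seed = 44))
#> [1] 0.939

# 4. which waveform strata drive the predictions?
strata_importance(shap_contributions(fit, cal[1:200, ]))
#> strata importance: lower 0.025, middle 0.016, upper 0.959
```

The entropy readout says this stand is near the horizontal complexity cap of
a 25-m footprint (CE_XY ≈ 6.4 of a maximum near 6.3–6.5 for fully occupied
footprints) and carries substantial vertical structure (CE_Z ≈ 6.8). The
conformal intervals are ~11–15% of the predicted value, and on this
synthetic table the model draws almost all of its information from the upper
waveform stratum.

There is also a small command-line front end in `inst/scripts/wsci`
(`wsci simulate-stand | entropy | rh | filter`).

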