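---
title: "Measuring and modelling canopy structural complexity with wsci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling canopy structural complexity with wsci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsci)
```

## The index and its assumptions

`wsci` treats forest structural complexity as the information content of a
footprint-sized point cloud. Each of the three orthogonal 2D projections of
the cloud (XY, XZ, YZ) is smoothed with an isotropic Gaussian kernel density
estimate, the density is evaluated on a regular lattice of spacing
$s = 0.10$ m, and the grid entropy

$$\mathrm{CE}_{2d} = -\sum_i \rho_i \ln(\rho_i)\, s^2$$

is a Riemann-sum estimate of the differential entropy of the smoothed point
density, in nats. The three planar entropies combine as
$\mathrm{CE}_{XYZ} = \sqrt{\mathrm{CE}_{XY}^2 + \mathrm{CE}_{XZ}^2 +
\mathrm{CE}_{YZ}^2}$, with the horizontal component $\mathrm{CE}_{XY}$ and
the vertical component $\mathrm{CE}_Z = (\mathrm{CE}_{XZ} +
\mathrm{CE}_{YZ})/2$ — a waveform instrument observes vertical structure in
a single integrated direction, so the two vertical planes are averaged.

Two consequences of this construction matter for interpretation. First,
differential entropy is maximised by the uniform distribution, so
$\mathrm{CE}_{XY}$ has a hard cap for a fixed footprint: a uniformly filled
25-m disk has analytic entropy $\ln(\pi \cdot 12.5^2) \approx 6.20$ nats,
and the kernel's boundary smoothing raises the measured cap to about
6.3--6.35 (the acceptance script recomputes this). Vertical entropy has no
such cap — it grows with canopy height. Second, entropies of concentrated
clouds can be negative; the Euclidean combination is still well defined.

Assumptions: clouds are ground-normalised (terrain removed upstream), the
footprint is clipped with a strict `<` radius test so boundary points are
handled deterministically, and point density is equalised by adaptive voxel
thinning before the KDE, so that scanner density does not masquerade as
complexity.

## Numerical choices

* **Bandwidth.** The kernel bandwidth follows the multivariate
  rule-of-thumb $h_d = \min(\hat\sigma_d, \mathrm{IQR}_d/1.34)\,n^{-1/6}$
  per axis, combined geometrically into a single isotropic value. A fixed
  `bandwidth` argument overrides the rule (used by the closed-form tests).
* **Lattice extent.** The data bounding box padded by three bandwidths;
  nodes with density below $10^{-12}$ are dropped from the sum — they
  contribute nothing but destabilise the logarithm. The three-bandwidth
  padding clips a fraction of a percent of the kernel tail mass; the
  lattice sum of $\rho_i s^2$ is attached to every result and is required
  by the tests to be within 5% of 1.
* **Voxel thinning.** One centroid per occupied voxel; the voxel edge is
  found by bisection so the retained count lands within 10% of the target
  (default 5000 per footprint, keeping the KDE cost bounded at 25-m scale).
  The voxel grid is anchored at the cloud's minimum corner, which makes
  thinning — and hence the whole index — invariant under rigid translation,
  and re-thinning at the stored edge and origin is the identity.
* **Tree traversal in double precision.** Boosted-tree predictions,
  Shapley contributions and conformal calibration all walk the dumped trees
  in R doubles, with features and thresholds aligned to their float32
  representations so the routing reproduces the training engine bit for
  bit. This is what lets the Shapley local-accuracy identity
  (base + contributions = prediction) hold to ~1e-12 rather than the
  single-precision 1e-5 of the engine's own contribution predictor, which
  the tests retain as an independent cross-check.

## The waveform model

`simulate_waveform()` weights each point by a Gaussian footprint
illumination ($\sigma_f = 6.25$ m, a 25-m nominal diameter treated as
$\pm 2\sigma$), bins the weights by height (0.15-m bins) and convolves with
a Gaussian system pulse ($\sigma_p = 2.35$ m). The convolution kernel is
normalised and tail mass is folded back into the end bins, so waveform
energy equals total point weight exactly — an invariant the tests assert.
These constants are configurable; they are plausible large-footprint values
rather than any instrument's calibrated ones.

RH percentiles are read from the cumulative energy, bottom up: RH$p$ is the
smallest bin height at which cumulative energy reaches $p\%$ of the total.
Because a Gaussian pulse has infinite tails, the percentile support is first
delimited by a signal threshold (bins below 1% of the peak amplitude are
outside the signal); without this, RH100 would sit ~4 pulse sigmas above
the highest return. Geolocation offsets between a waveform set and a point
cloud are recovered by exhaustive grid search maximising the mean
per-shot Pearson correlation (ties: smallest offset norm, then
lexicographic). Crossovers are retained only with ≥ 10 shots and mean
correlation ≥ 0.75, and shots pass the quality filter only with clean
processing flags, non-urban non-water surface, amplitude above 8× the
corrected noise deviation, sensitivity above 0.95 (0.98 in the tropics) and
a tree-covered PFT class.

One convention was genuinely open: whether the crossover correlation is
averaged per shot or pooled across bins. The per-shot mean is implemented —
it weighs every shot equally regardless of waveform length.

## Modelling, selection and uncertainty

`wsci_fit()` trains one gradient-boosted regression per PFT, predicting
`ce_xyz` (WSCI), `ce_xy` or `ce_z` from the 101 RH features.
Cross-validation folds partition *sites*, not rows, so validation data
always come from unseen locations; sites are assigned greedily (largest
first, seeded order) to balance fold row counts. The search keeps only
configurations whose mean train/validation gaps in RMSE **and** R² are
below 5% and then minimises validation RMSE; ties prefer fewer trees, then
shallower ones. The gap is *relative* (|train − val| / train, in percent) —
the scale-free reading of the constraint; an absolute variant is available
via `gap_type`. The default grid is deliberately small (3 × 2 × 2 × 3 × 2)
with fixed regularisers (`min_child_weight = 20`, `lambda = 5`); at desk
scale, only strongly regularised shallow configurations generalise across
sites well enough to be admissible, which is the intended behaviour of the
constraint.

Conformal calibration is Mondrian: calibration predictions are cut into
equal-count bins (default 10, merged to keep ≥ 20 rows each), and each bin
gets the finite-sample quantile
$\lceil (n_b + 1)(1-\alpha) \rceil$-th smallest absolute residual. Binning
on the *predicted* value — the paper-style taxonomy variable is not
observable at deployment — keeps intervals usable for every new footprint
while absorbing heteroskedasticity. The relative interval size is
(upper − lower)/prediction. Coverage is a marginal guarantee under
exchangeability of calibration and test rows: with ~800 calibration rows
the realised coverage of a single 1000-row holdout fluctuates a little
around its ≥ 95% expectation, which is inherent to split conformal, not a
defect of the calibration.

Shapley attributions use the exact path-dependent tree-Shapley recursion;
per-feature importance is the mean absolute contribution over the rows of
interest ("accumulated" importance admits several readings; mean |φ| is the
standard one and is what `strata_importance()` normalises into lower
(≤ RH33, boundary inclusive), middle (RH34–RH66) and upper (> RH66)
fractions). Where a "top decile" of RH features is needed, RH91–RH100 is
the default reading (RH90–RH100 is one index wider and changes little).

## The synthetic generators — what they do and do not emulate

`generate_stand()` builds stands from primitives: a noisy ground plane,
cone or ellipsoid crowns sampled on surface and interior (interior fraction
0.3), an optional shrub layer, and `n_layers` vertical strata. Stem density
is *per stratum* — multi-layered stands carry canopy, mid-storey and
understory stems on top of each other, which is what makes vertical entropy
grow monotonically with layering, as it should. Layer $l$ of $L$ scales the
drawn height by $0.3 + 0.7\,l/L$, so the top stratum keeps the full height
distribution. The generator does **not** emulate terrain, occlusion,
radiative transfer, species allometry or sensor noise; passing tests on
these stands demonstrates the pipeline's mathematical behaviour, not
instrument-level fidelity on real forests.

`simulate_rh_table()` generates RH-to-complexity training tables directly:
10 sites with mean canopy heights uniform on 18–32 m, within-site height
spread of 10 m (truncated at 3 m), Beta-CDF-shaped RH profiles with random
curvature, and targets built from smooth height and foliage-diversity
relationships. The vertical component carries noise inversely proportional
to the signal, reproducing the empirical pattern that low-complexity
footprints have larger *relative* prediction errors — this is what the
Mondrian intervals are for. The horizontal component is tied to the profile
only weakly and nonlinearly, so fitted models predict vertical complexity
better than horizontal complexity, mirroring what a vertical-only
instrument can and cannot constrain. Site parameters are drawn separately
(`simulate_rh_sites()`) from row draws, so that exchangeable holdouts can
be regenerated for any chosen sites — the conformal guarantee is only
meaningful against such a holdout.

## Problem sizes and runtime

The test-suite and acceptance problem sizes are chosen for a laptop-class
single CPU: 4000-row training tables over 10 sites, 700–2000-point voxel
targets for per-footprint entropy, 20 seeded geolocation fixtures with
10 shots each, and a 5 × 5-fold grid search over a handful of
configurations. The full suite runs in about two minutes; the acceptance
script in under one.

## Known limitations

* LAS/LAZ files are not read directly; point clouds enter as delimited
  x,y,z tables (`read_cloud_xyz()`).
* The strata composite is an in-memory 3-band array with extent attributes,
  not a georeferenced file format.
* Tree-based Shapley values are path-dependent (cover-weighted)
  attributions; interventional SHAP and interaction values are out of
  scope.
* Equal-area global tiling is approximated by a square grid in projected
  coordinates; grid aggregation is exact only up to that approximation.
* The generators are statistical stand sketches. Results on them bound what
  the pipeline can do under its own assumptions; transfer to real ALS/GEDI
  archives depends on geolocation quality, sensor noise and biome coverage
  that the synthetic stands deliberately idealise.
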