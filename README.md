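# msomscale

Biodiversity loss from land-use change is usually measured at single sites,
but converted habitats everywhere tend to fill with the same tolerant,
wide-ranged species while narrow-ranged specialists disappear. That biotic
homogenization makes regional losses systematically worse than local ones.
`msomscale` is an R package for quantifying this scale dependence from
presence–absence point-count data: it fits a biogeographically constrained
multi-species occupancy model (bMSOM) with imperfect detection, predicts
species occupancy on a 2-km grid under hypothetical all-forest and
all-pasture scenarios, and turns those predictions into cross-scale loss
metrics, hexagon-grid beta-diversity regressions and generalized
dissimilarity models (GDMs). A synthetic-avifauna generator with the same
statistical structure (clustered paired forest/pasture point counts, four
visits, multiple observers) makes every stage testable without field data.

## The core quantities

* **Occupancy model.** For species *s* at point *i*, presence
  *z<sub>si</sub>* ~ Bernoulli(ψ<sub>si</sub>) and visit-level detection
  *y<sub>sij</sub>* ~ Bernoulli(z<sub>si</sub> p<sub>sij</sub>); the fitted
  likelihood marginalizes *z*. Logit ψ includes species-standardized
  elevation (±1 at the species' elevational limits), a monotonic effect of
  distance-to-range, land use, traits and land-use × trait interactions,
  plus species/family/cluster/subregion random effects. Species–point pairs
  are clipped at 160 km distance-to-range and standardized elevation
  (−3, 3).
* **Sensitivity.** S = Σψ<sup>forest</sup> / Σψ<sup>pasture</sup> over any
  scope; community loss is the 25th/50th/75th percentile of S over the
  thresholded species pool (occupancy ≥ 0.2 somewhere in the scope), with
  percent decline 100(1 − 1/Q).
* **Scaling.** Multiplicative beta-diversity (gamma over mean pixel alpha)
  on randomly rotated/offset hexagon grids from 290 to 70,000 km²,
  regressed per posterior draw against the log-ratio of regional to mean
  local loss.
* **Turnover.** GDMs with a negative-exponential link and three monotone
  I-splines per predictor (knots at min/median/max) on geographic distance,
  elevation, precipitation and valley/mountain barrier separations, with
  Bayesian-bootstrap uncertainty and a detection-corrected variant.

## Worked example

```r
library(msomscale)

L    <- make_landscape(extent_km = c(40, 40), n_regions = 4, seed = 3)
pool <- make_species_pool(L, n_species = 25, n_families = 8, seed = 2)
des  <- make_sampling_design(L, n_clusters = 20, seed = 4)
tr   <- simulate_truth(L, pool, des, seed = 5)
det  <- simulate_detections(tr, des, pool, seed = 6)

fit  <- fit_occupancy(det, tr$features, pool, des, method = "mcmc",
                      chains = 2, warmup = 100, iter = 100, seed = 1)
fit
#> msom_occfit (mcmc): 918 species-point pairs, 680 parameters, 200 stored draws
#>   max split R-hat: 4.333 ; min bulk ESS: 15

cube <- predict_occupancy(fit, L, pool, draw_ids = 1:5, seed = 1)
cube
#> msom_cube: 25 species x 400 pixels x 2 scenarios x 5 draws

S <- species_sensitivity(cube, draw = 1)
community_metric(S[species_pool(cube, tau = 0.2, draw = 1)])
#>      q    value decline_pct
#> 1 0.25  1.20340    16.90211
#> 2 0.50  3.11044    67.85021
#> 3 0.75 21.63417    95.37768
```

The metric table reads: across the landscape-wide species pool at the 0.2
occupancy threshold, the median species would occupy about 68% fewer cells
if the landscape were pasture instead of forest, and the more sensitive
75th-percentile species about 95% fewer. (The R-hat line is honest output
from these deliberately short demonstration chains: weakly identified
random-effect coordinates are flagged; lengthen the chains for clean
diagnostics.) `pooling_trajectory()` then shows
how these metrics grow as biogeographic regions are pooled,
`hex_scaling_records()` + `fit_scaling_regression()` relate excess regional
loss to beta-diversity, and `fit_gdm()` / `bayesian_bootstrap()` fit the
turnover models. `run_pipeline()` (or
`Rscript inst/scripts/run_pipeline.R --config cfg.yaml --out dir`) chains
all stages with a hashed artifact manifest.

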