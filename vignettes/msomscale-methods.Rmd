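---
title: "Cross-scale biodiversity loss: models and methods in msomscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-scale biodiversity loss: models and methods in msomscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msomscale)
```

## The problem

Field assessments of biodiversity loss from land-use change are overwhelmingly
local. When converted habitats everywhere fill up with the same tolerant,
wide-ranging species while narrow-ranged specialists drop out (biotic
homogenization), the loss measured over a large region can be much worse than
the loss at any single site. `msomscale` implements the full analytical chain
needed to quantify that scale dependence on presence–absence point-count
data: a detection-corrected multi-species occupancy model, species-sensitivity
and species-pool metrics, region-pooling curves, hexagon-grid beta-diversity
regressions, and generalized dissimilarity models (GDMs) with biogeographic
barrier covariates. A first-class synthetic-data generator reproduces the
statistical structure of such a study (clustered point counts in paired
forest/pasture, four visits, several observers), so every stage is testable
end to end without any field data.

## The occupancy model

For species $s$ at point $i$, latent presence is $z_{si} \sim
\mathrm{Bernoulli}(\psi_{si})$ and the visit-$j$ observation is $y_{sij}
\sim \mathrm{Bernoulli}(z_{si}\, p_{sij})$. The likelihood marginalizes
$z$:

$$\Pr(y_{si\cdot}) = \psi \prod_j p_j^{y_j}(1-p_j)^{1-y_j} +
(1-\psi)\,\mathbb{1}\{\textstyle\sum_j y_j = 0\}.$$

The occupancy logit combines species-standardized elevation (linear and
quadratic, with a −1/+1 "lowland" modifier interacting with both terms for
species whose elevational minimum sits at zero), a monotonic ordinal effect
of binned distance-to-range (a scale coefficient times the cumulative sum of
a simplex over 8 equal-width bins spanning ±160 km; the bin count and window
are configurable), land use (forest = +1, pasture = −1), species traits and
land-use × trait interactions, and random effects: species and family
intercepts, species elevation slopes, species and family land-use slopes,
and species-by-cluster and species-by-subregion intercepts (subregions are
axis-aligned 20-km grid cells). Detection combines observer contrasts, a
time-after-sunrise slope, land use and traits, with species, family and
species-by-observer intercepts plus species time slopes and species and
family land-use slopes. All binary predictors are coded −1/+1 so prior
pushforward densities do not depend on reference-category choices.

**Biogeographic clipping.** Only species–point pairs with
distance-to-range < 160 km, species-standardized elevation strictly inside
(−3, 3), and an in-season survey date enter the model. Distance-to-range is
signed (negative inside the range) and computed only against range in the
point's topographic unit; a species with no range in the unit is clipped.
Standardized elevation maps the species' elevational limits to −1 and +1.

**Priors.** Zero-centred Gaussians throughout: scale 1.5 for intercepts and
the monotonic-effect scale, 1 for slopes; half-Normal(1) for random-effect
standard deviations; uniform simplex for the monotonic increments. These are
deliberately weakly informative on the logit scale: with half a dozen ±1
covariates they leave ≥90% of prior pushforward mass on occupancy
probabilities inside (0.01, 0.99) rather than piling up at 0/1.

**Fitting.** The backend (in C++ via Rcpp) evaluates the marginal negative
log posterior and its analytic gradient. `method = "map"` runs limited-memory
BFGS over all coefficients and random-effect values with the random-effect
standard deviations held at their prior scales (optimizing them jointly at
the mode would collapse them toward zero, the usual pathology of joint
penalized modes). `method = "mcmc"` runs an adaptive Metropolis-within-Gibbs
sampler initialized at the MAP: scalar updates exploit the fact that each
parameter touches only a subset of species–point pairs (the likelihood
factorizes over pairs), proposal scales adapt toward a 0.44 acceptance rate
during warmup, and dedicated *translation moves* shift a fixed effect
against its centred random-effect vector along the likelihood-invariant
direction — the classic slow direction of centred hierarchical models.
Split R-hat and a bulk effective-sample-size estimate are recorded for every
stored parameter; parameters at R-hat ≥ 1.02 are flagged with a warning, not
an error. With short chains many weakly identified random-effect coordinates
are flagged while the global effects of interest mix well; users wanting
clean diagnostics throughout should lengthen the chains.

**Prediction.** Occupancy is predicted on the 2-km pixel grid for
hypothetical all-forest and all-pasture landscapes. Because one 2-km pixel
contains sixteen 500-m cells — the footprint of one sampling cluster — the
cluster-level effect is sampled 16 times per pixel, inverse-logit
transformed, and averaged on the probability scale. One subregion effect is
drawn per species and subregion and shared across the pixels of that
subregion (for unsampled subregions it is re-sampled from its fitted
distribution). Clipped species–pixel pairs get occupancy 0.

## Sensitivity, pools and pooling curves

Species sensitivity over a scope is $S = \sum_i \psi^{\text{forest}}_i /
\sum_i \psi^{\text{pasture}}_i$; $S > 1$ means the species loses from
conversion. Species pools are thresholded at occupancy 0.2 (alternates 0.1
and 0.3) on at least one pixel of the scope in either scenario. Community
metrics are the 25th/50th/75th percentiles of $S$ over the pool (linear
interpolation between order statistics; the quantile rule is a package
choice) with percent decline $100(1 - 1/Q)$. For the multi-region analysis,
$S$ is computed study-wide and the pools select species; for the hexagon
analysis both $S$ and pools are recomputed within each cell. Species whose
pasture total is below 1e−9 within a scope are excluded from that scope's
distribution with a count. Region pooling uses 1,000 random region
sequences and up to 100 posterior draws by default; relative sensitivity is
metric(pooled-$k$)/metric(all), exactly 1 at $k = R$, and the "percent more
severe" summary is $100(\text{metric}_{\text{all}}/\text{metric}_k - 1)$
averaged over sequences and draws (the mean, not the median, is the default
aggregation).

## Hexagon scaling

Hexagonal grids span a ladder of nominal areas; the default ladder
{290, 860, 2,600, 7,800, 23,000, 70,000} km² fills the printed 290–70,000 km²
range with six log-spaced scales (the intermediate values are a package
choice). Each grid is uniformly rotated in [0°, 60°) and offset within one
cell span, re-randomized at each posterior draw; pixels belong to the
hexagon containing their centre, and cells whose member-pixel area covers
< 60% of the hexagon are dropped. Multiplicative beta-diversity is gamma
(cell-pool richness) over mean alpha (pixel-pool richness), which is ≥ 1 by
construction. Excess regional loss is the log-ratio of the cell-scale
percent decline to the mean of the member pixels' local declines (averaging
declines, not sensitivities, is the default; both are implemented).
Cell–draw pairs with non-positive loss at either level are excluded and
counted. The per-draw line of best fit is closed-form OLS — the grid is a
census of the domain, so no within-draw standard errors — and uncertainty
bands are pointwise 90% intervals of the fitted lines across draws.

## GDMs and barriers

Pairwise Sørensen and Simpson (turnover) dissimilarities are modelled with a
negative-exponential link, $\hat d = 1 - e^{-\eta}$, where $\eta$ is a
non-negative intercept plus, per predictor, three order-2 (piecewise
quadratic) I-spline basis functions knotted at the predictor's minimum,
median and maximum — order 2 is the convention of reference GDM software.
Pairwise predictors (geographic distance, barrier separations) are splined
directly; site-level predictors (elevation, precipitation) enter as
|f(x₁) − f(x₂)|. Coefficients are fitted by box-constrained (≥ 0)
quasi-Newton weighted least squares with an analytic gradient, so every
partial response is monotone non-decreasing and $\hat d \in [0, 1)$.

The valley barrier between two sites is 0 on the same mountain range and
otherwise the elevation of the lower site; the mountain barrier is 0 on the
same side of the major biogeographic divide and otherwise a ceiling constant
(default 4,100 m, configurable because it is dataset-specific — the highest
elevation sampled) minus the elevation of the higher site, floored at 0.

Uncertainty uses the Bayesian bootstrap: per replicate (default 400),
site-level Dirichlet(1,…,1) weights are mapped to pair weights as the
renormalized product of the two sites' weights (the site-to-pair mapping is
a package choice). The detection-corrected variant samples the latent state
from its conditional — certain presence where detected, otherwise
$\psi\prod_j(1-p_j) / [\psi\prod_j(1-p_j) + 1 - \psi]$ — once per posterior
draw and fits a single bootstrap replicate to each draw. Observed
communities pool detections across visits (one community per point).

## The synthetic generator: what it does and does not emulate

The generator builds planar landscapes (km on a plane, Euclidean distances;
no projections), with elevation as a sum of Gaussian ridges, contiguous
region bands and topographic-unit bands that cut across each other, and a
smooth precipitation surface. Species get contiguous ranges (a configurable
endemic fraction drives beta-diversity), elevational niches with a lowland
fraction pinned to minimum 0, synthetic families, and −1/+1 binary plus
standardized continuous traits from a configurable named set (the exact
trait list of any particular field study is supplementary material, so the
set is parameterized rather than hard-coded). Designs use paired
forest/pasture clusters (pairing at < 200 m elevation and < 21 km distance),
2–3 points per cluster at ≥ 200 m spacing, 2–4 visits and a small observer
team; all species default to resident (date gating is implemented but off).
Truth and detections follow exactly the model above, so parameter-recovery
tests are well-posed. What passing tests on these data do *not* show:
robustness to range-map error, taxonomic mismatch, spatially structured
detection heterogeneity, abundance-driven detection, or non-Gaussian
random-effect distributions — none of which the generator produces.

## Numerical choices and test-scale conventions

Degenerate inputs are handled explicitly: empty pools raise or flag rather
than silently propagate; zero-species sites keep their pairs with a d = 1
convention and a flag; cells losing all pixels to the overlap rule warn;
constant GDM predictors are dropped and an all-degenerate design falls back
to an intercept-only fit. Seeds thread through every stochastic stage
(`child_seed` derives bounded per-stage seeds), and all generators are
bit-reproducible given (config, seed).

Test and example problem sizes are deliberately modest — landscapes of
20–60 km, tens to 150 species, MAP or 2 × (150–250)-iteration chains —
chosen so the full suite exercises every stage at depths where the
simulation-based calibration properties (interval coverage, rank
correlation of species effects ≥ 0.8) are empirically verified. The
calibration experiment for the land-use effect uses 150 species, 80
clusters × 3 points and 4 visits, generated from intercept −0.5, land-use
effect 1.0, species-intercept SD 1, species-land-use SD 0.75 and constant
detection ≈ 0.5 — a realistic signal-to-noise regime for community
occupancy data at that effort.

## Known limitations

MAP mode gives point estimates only; interval statements need MCMC. The
Metropolis-within-Gibbs sampler mixes slowly for deep hierarchical scale
parameters on very sparse data (flagged by R-hat); Hamiltonian samplers
would do better where available. Hexagon overlap uses pixel membership, so
very small cells relative to the pixel size are quantized. The GDM fit
minimizes squared error on the dissimilarity scale rather than maximizing a
binomial likelihood, matching standard GDM practice but inheriting its
heteroscedasticity. The pipeline's `run_pipeline()` targets reproducible
artifact generation, not workflow-engine integration.
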