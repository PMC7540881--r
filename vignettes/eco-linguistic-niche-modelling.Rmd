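---
title: "Eco-linguistic niche modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-linguistic niche modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elnm)
```

## The model

An *eco-linguistic niche* (ELN) treats the territory of a language group the
way ecological niche modelling treats a species range: village localities
inside the group's territory are presence records, the environment is a
stack of gridded covariates, and a presence-only suitability model estimates
the range of environmental conditions the group occupies. The output is a
per-cell suitability score in [0, 1] — *not* a calibrated occupancy
probability, only a relative ranking of environments.

The covariate stack holds 26 layers: the 19 standard bioclimatic variables
(bio1–bio19, derived from monthly minimum/maximum temperature in °C and
precipitation in mm by the ANUCLIM-style definitions in `compute_bioclim()`)
and 7 terrain layers derived from a DEM (`terrain_derivatives()`): elevation,
Horn slope and aspect, D8 flow direction, terrain ruggedness index (TRI),
topographic position index (TPI) and 9-cell roughness. All 26 variables are
retained even though many are correlated: different regions are dominated by
different correlated subsets, and the consensus step plus omission
thresholding limit overfitting.

### Suitability algorithms

Three deterministic algorithm families stand behind one interface
(`algorithm_config()`, `fit_niche_model()`, `predict()`):

* **bioclim** — the classic envelope: 1 inside the core box
  (mean ± `sd_cutoff`·sd on every variable), 0.5 inside the min–max box,
  else 0. The default `sd_cutoff = 0.674` makes the core the
  half-probability envelope of a normal distribution.
* **envelope_score** — the fraction of variables inside the training
  min–max range; a graded relaxation of the envelope.
* **env_distance** — variables are rescaled to [0, 1] by their *study-area*
  range (the prediction domain, so the rescaling is shared by every cell);
  suitability is `max(0, 1 − d/d_max)` with `d` the distance to the mean of
  the `n_nearest_points` nearest training points. `d_max` is
  `max_distance_fraction` (default 0.5) times a metric-specific maximum:
  `sqrt(p)` for Euclidean, 1 for Gower (mean of range-normalised absolute
  differences) and Chebyshev (their maximum), and — because the Mahalanobis
  distance has no finite bound — the largest Mahalanobis distance observed
  over the study area.

Determinism is deliberate: ensemble consensus only needs several independent
[0, 1] predictions with evaluation scores, and deterministic members make
every downstream contract exactly testable. New algorithms can be added by
registering another config/fit/predict method.

### Evaluation and weighted elitist consensus

Presence-only evaluation compares suitability at held-out presences against
a random background sample (default 10× the presences, capped at 10,000
cells, excluding presence cells). Three scores are computed per model:
accuracy at a 0.5 threshold, rank-based AUC (ties count one half), and the
bootstrap partial-ROC ratio — the mean, over presence resamples of 50%, of
the model's partial AUC over the high-sensitivity region (sensitivity
≥ 1 − E, default E = 0.10) divided by the null diagonal's partial area on
the same region. Ratios near 1 indicate no signal.

The consensus (`weighted_elitist_consensus()`) is elitist and weighted:
models are ranked by held-out AUC (ties broken by partial-ROC ratio, then
model id), the top half (rounded up) is retained, weights are proportional
to AUC (or equal), and the weighted maps are added cellwise. Because
weights sum to one, the consensus is a convex combination and stays in
[0, 1].

### Omission threshold

To limit the influence of unrepresentative occurrences, suitabilities below
a fixed-sensitivity threshold are reduced to zero: τ is the (k+1)-th
smallest occurrence suitability with `k = floor(s·n)` (default sensitivity
`s = 0.10`), so at most a fraction *s* of occurrences is omitted. Order
statistics are used directly — no interpolation — so the contract is exact.

One pipeline-level design choice deserves emphasis: `fit_consensus_eln()`
computes τ from the *held-out* occurrence half, not from all occurrences.
The deterministic algorithms score their own training cells exactly 1.0, so
a threshold over the pooled set would sit near the 24th percentile of the
generalisation distribution and omit roughly twice the nominal fraction.
The threshold function itself is agnostic — it thresholds whatever
occurrence set it is given.

### Niche space, overlap and patterns

A single PCA (`fit_env_pca()`) of all valid study-area cells, on the
correlation matrix because the variables carry heterogeneous units, defines
one common ecological space; each niche is projected into it as the cloud
of cells with suitability above 0.9 (`project_eln()`), a cutoff that
suppresses the low-value background the consensus averaging produces.
Clouds are summarised by inertia ellipses calibrated to contain 61% of a
Gaussian cloud (`inertia_ellipse()`; covariance scaled by the χ²(2)
quantile).

Niche overlap is measured on suitability maps normalised to sum to one over
shared valid cells: Schoener's `D = 1 − ½Σ|p₁ − p₂|` and Hellinger-based
`I = 1 − ½Σ(√p₁ − √p₂)²`, both 0 (disjoint) to 1 (identical).
Dissimilarity is `1 − overlap`; `cluster_niches()` applies complete-linkage
agglomeration to Euclidean distances between the dissimilarity-matrix rows
(each niche characterised by its full overlap profile), via `hclust`.

*Eco-linguistic patterns* (ELPs) formalise "groups sharing a niche" as an
explicit rule (`identify_elps()`): link two groups when geographic overlap
(Jaccard of the thresholded ranges, after accessibility filtering) is at
least `g_min = 0.4` *and* environmental overlap D is at least
`d_min = 0.6`; patterns are the connected components (so chains merge
transitively). The original analysis identified patterns by expert
inspection; a reproducible pipeline needs a stated rule, and both
thresholds are configurable and reported. The accessibility filter keeps
only 8-connected range components that intersect the group's territory —
plus, for maritime (seafaring) families, components touching the sea.

### Potentials, growing season and risk

Family-level *eco-linguistic potential* is the cellwise mean suitability
over all of a family's groups; the differential map is the difference of
two family potentials and is bounded in [−1, 1]. The growing season counts
months whose mean temperature strictly exceeds 6 °C and whose precipitation
(mm) strictly exceeds twice the temperature (°C) — evaluated
multiplicatively (`prec > 2·t`), never as a ratio, so sub-zero temperatures
need no special case. Ecological risk is the reciprocal of the regional
mean growing season, flagged undefined when that mean is zero.

## The synthetic world

`generate_synthetic_world()` builds a complete study system with known
ground truth, emulating the *structure* of an equatorial island world:

* a 200 × 200 geographic grid (~0.055° cells) with a northern sea margin
  (~15% of rows), a low offshore island, and elevation rising southwards to
  a ~3,400 m ridge following a power-law hypsometry (gentle coastal shelf,
  steep highland rise);
* terrain ruggedness that grows with elevation (near-flat coastal plain,
  rugged ridge), implemented as elevation-scaled noise with a 3-cell
  length-scale so its statistics are stationary across the map;
* monthly temperature driven by a 5.5 °C/km lapse rate with a mild seasonal
  cycle (tropical amplitude ±0.8 °C) and 0.2 °C spatial noise; monthly
  precipitation with a maritime plateau (~+120 mm) fading inland, a mild
  orographic term, a ±60 mm seasonal cycle and 8 mm spatial noise;
* language groups planted in elevation strata separated by unclaimed gaps
  (highland > 2,600 m: 3 groups; midland 1,200–1,700 m: 2; lowland
  400–800 m: 1; coastal ≤ 120 m: 2 maritime groups). Groups in one stratum
  occupy adjacent longitudinal slices of the same environmental band — a
  planted multi-group pattern; single-group strata are planted singletons.
  Each stratum covers only 12–20% of the land so that presence/background
  AUC can meaningfully exceed 0.9;
* villages sampled uniformly *in geographic space* inside each territory
  (60–120 per group), so occurrence sampling carries the same geographic
  bias as real village gazetteers.

The ground-truth niche of a group is the binary grid of cells inside its
stratum's elevation interval. Everything is reproducible from a single
seed, and seeded helpers save and restore the caller's RNG state.

What the generator does *not* emulate: digitisation error in territory
polygons, spatially clustered (road- or river-biased) village samples,
climate interpolation artefacts, anisotropic weather systems, and
territories defined by anything other than environment. Passing recovery
tests therefore show that the pipeline's machinery is correct and that
environmentally planted structure is recoverable at realistic sample sizes
— not that real language territories are environmentally determined (the
original study's substantive finding was largely the opposite).

## Numerical choices

* Quarters in the bioclim derivation wrap across the year boundary;
  quarter ties resolve to the earliest starting month. bio4 uses the
  sample (n−1) standard deviation. bio15 is the plain coefficient of
  variation (0 when mean precipitation is 0); bio3 is defined as 0 when the
  annual range is 0.
* Aspect is undefined on flat cells; inside an assembled stack it is
  encoded as −1 (a value outside [0, 360)) so flat cells survive the
  shared nodata mask. Flow-direction ties go to the lowest D8 code;
  diagonal drops divide by √2. Terrain `xres`/`yres` are horizontal
  spacings in elevation units; the synthetic world converts degrees at
  111.32 km/degree (equatorial).
* Boundary points count as inside a polygon; a point inside several
  polygons goes to the smallest by area (deterministic tie-break).
* A singular Mahalanobis covariance is ridge-regularised by
  `1e-6 · trace/p` on the diagonal, with a warning.
* The study-area rescaling of `env_distance` treats a zero-range
  (constant) variable as contributing no distance.
* PCA component signs are fixed so each component's largest-magnitude
  loading is positive.
* Per-stage seeds are derived arithmetically from the single pipeline seed;
  background sampling, splits and bootstraps are all reproducible.

## Problem sizes

The test suite exercises formula oracles on small random inputs (seconds),
the threshold contract on 100 random maps, pipeline behaviour on a 60 × 60
world, and full recovery on the default 200 × 200 world with 8 groups
(about half a minute on one core). Recovery levels on the default world are
typically: mean Schoener's D between estimated and planted niches ≈ 0.8 or
above, planted pattern partition recovered exactly or nearly so (adjusted
Rand index ≥ 0.8), and held-out consensus AUC ≈ 0.9 or above per group;
exact values vary a little with the seed, as the acceptance script shows.

## Known limitations

* The algorithm family is a deterministic stand-in for the heterogeneous
  ensembles (GARP, MaxEnt, neural networks, support-vector machines, …)
  used in production niche-modelling suites; it reproduces the consensus
  *contract*, not those algorithms' behaviour.
* Raster I/O is the plain-text ESRI ASCII grid; there is no on-the-fly
  reprojection, and grids must align exactly (nearest-neighbour resampling
  must be requested explicitly by the caller).
* Geographic overlap, accessibility and components are computed on the
  raster grid in geographic coordinates; no geodesic area weighting is
  applied, which slightly over-weights poleward cells on large extents.
* The ELP rule is a thresholded graph — transitive chains can merge
  environmentally distant groups through intermediaries, which is the
  documented (and monotone) behaviour, not a bug.
* Per-group language counts are only known for singleton patterns in the
  packaged metadata; multi-group pattern language totals are carried as
  printed and `diversity_summary()` reports NA rather than a fabricated
  per-group split.
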