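---
title: "Network buffer methods, built-environment measures and their comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network buffer methods, built-environment measures and their comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`bufcomp` quantifies how the choice of street-network buffering method changes
(a) built-environment exposure measures and (b) their estimated associations
with physical-activity outcomes. Everything operates on planar street networks
in projected meter coordinates; the package never reprojects — delivering
metric coordinates is the caller's responsibility, because all buffer
distances are metric.

The pipeline for one participant is:

1. **Snap** the home coordinate to the closest point on any walkable edge
   (Euclidean; ties broken by lowest edge id, then lowest offset). Walkability
   is an edge attribute derived from a configurable road-class deny-list
   (default `limited_access_highway`, `highway_ramp` — road classes
   pedestrians may not traverse). Snaps beyond a configurable distance
   (default 500 m) raise a warning but are still returned: a remote
   participant is a data-quality signal, not an exclusion rule.
2. **Reach**: single-source shortest-path expansion to a network-distance
   cutoff (default 1000 m, a common operationalization of walking distance)
   from the snapped origin. The origin splits its host edge, partial edges are
   kept as offset intervals, and an edge entered from both ends contributes
   the union of its partial reaches, merged so no length is double counted.
   Node distances come from Dijkstra (igraph); the partial-edge interval
   arithmetic is the package's own and is verified in the test suite against
   an independent oracle that densifies every edge into 1 m pieces.
3. **Buffers**: three polygon operators over the reached segments (below).
4. **BEMs**: eleven measures per buffer (next section).
5. **Comparison**: paired *t* tests and MSE on participant-matched BEM
   vectors; mixed-model associations per outcome; coefficient z tests;
   significance-agreement tables.

# The three buffer operators

All three are derived from one scalar field: the exact Euclidean distance
`D(x)` from a grid cell center `x` to the nearest reached street segment,
evaluated with a small compiled kernel on a regular metric grid.

* **sausage**: `D <= trim`. This is the Minkowski sum of the reached
  centerlines with a disk of radius `trim`, i.e. the classic line-based
  buffer, dissolved into one multipolygon.
* **detailed-trimmed**: morphological closing of the sausage by a disk of
  radius `closing_radius_dt - trim`, holes retained. Closing fills gaps
  narrower than twice the closing radius, which is exactly the behavior of a
  trimmed service-area polygon bridging nearby parallel streets.
* **detailed**: closing by the larger radius `closing_radius - trim` followed
  by filling all interior rings, emulating the block-wrapping service-area
  polygon.

The commercial algorithms behind the detailed and detailed-trimmed polygons
are proprietary, so these closings are documented surrogates, built to have
three well-defined, distinct and reproducible operators rather than
bit-compatibility with any particular GIS release. The closing identity
`(A dilated to D <= trim + r) eroded by r = closing(A, disk(r))` makes the
surrogates cheap: dilation is a threshold of the same distance field, and the
erosion uses the Euclidean distance transform (`EBImage::distmap`).

**Default radii.** `closing_radius_dt = trim + 25` and
`closing_radius = trim + 275` (i.e. 50 m and 300 m at the default 25 m trim).
The 25 m net closing fills street-to-street slivers but not 100–150 m blocks;
the 275 m net closing wraps typical block sizes entirely. Expressing the
defaults relative to the trim keeps the construction valid at the 75 m trim
(a fixed 50 m would violate the `closing_radius >= trim` precondition there).
The radii are configuration parameters; they were chosen once so that the
qualitative area ordering sausage < detailed-trimmed < detailed emerges on
block-structured networks, and are not tuned beyond that.

**Numerical choices.**

* Grid resolution `resolution` (meters per cell, default 2; 1 in
  precision-sensitive tests, 3 in the demo pipeline). Area error scales with
  boundary length times cell size; on the closed-form straight-road fixture
  the sausage area is reproduced to about 0.01% at 1 m resolution. The grid
  plays the determinism role that a fixed circle-discretization count plays in
  vector buffering implementations.
* The grid is **lattice-anchored**: cell centers sit at `(k + 1/2) * h` in
  each axis, so an axis-aligned street at an integer coordinate never has
  cell centers exactly on the `D = trim` contour, and reruns as well as
  different participants share one global lattice.
* Buffer **area** is cell count times cell area. The vector outline traced
  for export follows cell boundaries exactly (a marching-squares edge walk
  with left-turn preference at saddle cells), so the shoelace area of the
  exported MultiPolygon equals the reported area to floating-point precision.
* Discrete erosion can violate the theoretical nesting
  sausage ⊆ detailed-trimmed ⊆ detailed by single boundary cells; the
  implementation restores it by unioning each larger buffer with the smaller
  one. `closing_radius = trim` degenerates exactly to the sausage buffer
  (erosion by zero is the identity).
* Degenerate inputs: an empty reach is an error naming the participant; a
  closing radius below the trim is a parameter error.

# The eleven measures

For a buffer `B`:

* **net residential density** — summed `residential_units` of included
  residential parcels divided by their summed full areas (units per
  *residential* km², not per buffer km²); 0 with a flag when no residential
  parcel is included.
* **intersection count / density** — walkable-network nodes of degree >= 3
  (threshold configurable; the field does not define "intersection"
  canonically) whose coordinates fall in `B`; density per km² of buffer.
* **transit / private-recreation count and density** — point features inside
  `B`, after optionally snapping each point to its nearest network location
  (default on). Snapping exists because destinations sit tens of meters off
  the centerline and a 25 m sausage would otherwise miss them; both modes are
  available for sensitivity analysis.
* **park count / total area** — parks intersecting `B` count with their
  *full* areas. All polygon features follow the any-intersection rule: a
  parcel or park is included if any portion of its geometry touches the
  buffer, and downstream arithmetic uses whole-feature attributes (a clipped
  mode is available as configuration for sensitivity).
* **land-use mix** — normalized entropy `-sum(p_i log p_i) / log(k)` of
  included full-parcel areas over the k = 4 configured categories
  (residential, retail, civic, recreational). The denominator uses the fixed
  configured k, not the number of categories present, which keeps the index
  below 1 when categories are absent; the "other" class is excluded from the
  shares by default. Both choices are configurable.
* **walkability index** — sum of sample z-scores of net residential density,
  land-use mix and intersection density, standardized within each
  (method, trim) group across the analysis sample; its sample mean is 0 by
  construction, and a zero-variance component is an error naming the
  component.

Density denominators are the buffer area for intersection/transit/recreation
densities and the included residential parcel area for net residential
density. Whether transit density should instead divide by land area is
ambiguous in the field; buffer area was chosen and is documented here.

# Statistical comparison

**Value comparison.** BEM vectors are participant-matched across methods, so
the *t* tests are paired (df = n − 1, two-sided). Identical vectors are
reported as `status = "identical"` with t = 0, p = 1; a constant non-zero
difference (zero variance) as `"degenerate"` with p = 0. MSE is the mean
squared element-wise difference.

**Association models.** `outcome ~ f(z(BEM)) + covariates + (1 | cluster)`
fitted by maximum likelihood with `lme4`. BEMs are standardized to z-scores so
coefficients are comparable across measures and methods. The default term is
linear — coefficient-level comparison requires a single slope — with a
fixed-df natural-spline option (`splines::ns`, omnibus Wald chi-square over
the basis) for shape diagnostics, since associations need not be linear. A
penalized-smoothness GAMM was deliberately not used: fixed-df bases keep the
reported coefficient well-defined and the fits fast enough for
calibration-by-simulation. All five outcomes are modeled with Gaussian errors
on their raw scales (day counts on 0–7, minutes per week untransformed); this
is a documented simplification — the day-count outcomes are bounded and the
minute outcomes skewed — whose consequences are checked empirically by the
type-I-error simulations in the test suite.

**Coefficient comparison.** `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a
two-sided normal p. The two fits share participants, so their estimates are
positively correlated and the independence form is conservative; no
correction is applied. Agreement status at alpha = 0.05 (no multiple-testing
correction) is tabulated per stratum and method pair as: pairs with at least
one significant fit, and pairs differing in significance, split by which
method was significant. The 25 m trim is the default reporting configuration;
75 m runs behind a configuration flag.

# The synthetic city

The generator exists so the full pipeline is testable without proprietary
cohort data. It emulates the *structure* the analysis assumes, not the look of
any real city:

* **network** — an (m+1) × (n+1) grid at `block_size` spacing (default 12 × 12
  blocks of 100 m) with each edge independently removed with probability
  `edge_prune_prob` and a fraction flagged limited-access. Pruning is the
  single knob that spans the low-to-high street-connectivity contrast;
  generation retries (up to 100 times) until the largest walkable component
  holds 80% of nodes so cohorts are never stranded.
* **features** — parcels tile block interiors (four per block by default)
  with classes drawn from configured shares and Poisson unit counts;
  transit/recreation points fall along streets at configured intensities per
  km with a perpendicular jitter (so snapping is exercised); parks occupy
  random blocks.
* **cohort** — homes placed just off streets; recruitment clusters from
  k-means on home coordinates (spatially compact, mimicking census-unit
  clusters); SES and walkability strata from median splits of a synthetic SES
  gradient and of *true walkability* computed in a fixed 1 km circular
  window — circular precisely so that no network buffer method is privileged
  by construction.
* **outcomes** — latent-Gaussian: linear predictor = intercept +
  `beta_walkability` × z(true walkability) + covariate terms + cluster
  intercept N(0, sd_cluster²) + N(0, sd_resid²), then mapped to the outcome
  support: day counts clamp the rounded predictor to 0–7, minute totals
  exponentiate a log-scale predictor. Default intercepts are anchored to
  pooled outcome means reported for comparable adult cohorts (about 3
  transport-walking days and 160 minutes, 2 leisure days and 110 minutes,
  2400 sitting minutes per week); effect sizes and variance components are
  plausible round values, chosen once.

What passing tests on this generator do **not** show: realism of IPAQ-style
response distributions (they are censored and heaped in real data),
multi-city heterogeneity, pedestrian infrastructure absent from road
centerline files, or GPS-derived activity spaces. The generator's job is
parameter recovery and calibration, not demography.

# Verification strategy and problem sizes

Every geometric and statistical operator is tested against an independent
oracle: densified-graph Dijkstra for the reach (20 random pruned grids,
1e-3 m agreement), a capsule closed form and Monte-Carlo union sampling for
buffer areas (0.5%), exhaustive point-in-polygon tallies for intersection
counts, closed-form entropy values for land-use mix, and
calibration-by-simulation for the inference layer (coefficient recovery at
n = 1000 with 50 clusters over 200 replicates; Wald and z-test type-I error
over 1000 and 2000 replicates). The packaged demo pipeline (200 participants,
12 × 12 blocks, seed 7, 3 m grid) is run twice in the acceptance suite to
assert byte-identical outputs, and doubles as the qualitative check that BEM
values differ across methods while associations agree. These sizes were
chosen to give stable Monte-Carlo estimates at interactive runtimes on a
single CPU.

# Known limitations

* The detailed/detailed-trimmed operators are morphological surrogates;
  their areas are not calibrated to any commercial implementation's output,
  only their ordering and qualitative behavior.
* Raster-based geometry: point-in-buffer decisions within half a cell of the
  boundary are resolution-dependent (documented per function; tests use finer
  grids where it matters).
* Gaussian outcome models on bounded/skewed outcomes; no turn restrictions,
  one-way streets or travel-time impedance in the network model; no
  multiple-testing correction in the agreement tabulation (deliberate, to
  keep the significance-agreement semantics).
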