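---
title: "Methods: ecological vulnerability assessment with ecovuln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecological vulnerability assessment with ecovuln}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecovuln)
```

## Scope and data model

`ecovuln` implements a complete raster pipeline for regional ecological
vulnerability assessment under the sensitivity–resilience–pressure (SRP)
framework: thirteen indicator layers spanning topography, land surface,
climate, vegetation, ecological vitality, economic development and human
activity are standardized, compressed into an ecological vulnerability
index (EVI) by principal component weighting, graded into five levels,
and analyzed for spatial clustering, drivers, and future dynamics.

Grids are plain double matrices with `NA` as the mask, a cell size in
metres and an upper-left-corner origin (rows increase southward). Files
are read and written as ESRI ASCII grids — a plain-text format that
round-trips bitwise at full double precision — with a JSON sidecar for the
coordinate-system tag and categorical legends. Internal computation is in
double precision throughout. Reprojection and resampling beyond block
aggregation are out of scope; inputs are assumed co-registered, and
`assert_aligned()` enforces that before every stack-level operation.

## Standardization and the indicator stack

Layers are standardized by extreme differences per epoch, over the
unmasked cells of each layer: positive indicators map to
$(a - a_{\min})/(a_{\max} - a_{\min})$, negative ones (mean annual
temperature, annual precipitation, NDVI, biological abundance — layers
X5–X8) to $(a_{\max} - a)/(a_{\max} - a_{\min})$. Extremes are taken
per epoch so that each year's PCA stands on its own; pooling extremes
across epochs is a caller decision (standardize before stacking).
A constant layer has no usable range and raises a degenerate-range error
rather than silently producing zeros.

Land use (X13) is categorical. It is first scored on the conventional
1–6 vulnerability scale — waters 1, woodland 2, grassland 3, cropland 4,
construction land 5, bare land 6 — and the scores then enter
standardization as a positive indicator, the only reading under which
"no polarity" is self-consistent: the assigned values themselves increase
with vulnerability. Whether to standardize the 1–6 scores or use them raw
is genuinely open; we standardize by default so every layer lives on
[0, 1], and the choice only rescales one PCA input.

Two standard constructions are provided for layers that usually arrive
pre-computed: soil erosion as the four-factor RUSLE product
$K \times LS \times R \times C$ (the mask is the union of the factor
masks), and landscape fragmentation as focal patch density — the number of
4-connected patches of the focal cell's land-use class inside a moving
window, divided by the window area. The patch-density surrogate is
deliberately simple and is *not* numerically equivalent to Fragstats
landscape metrics; it serves as a monotone fragmentation signal with the
correct extremes (1/window² inside uniform patches, rising with
interleaving).

## PCA weighting and the EVI

The EVI weights come from an eigendecomposition of the **correlation
matrix** of the standardized layers (all layers live on [0, 1] but their
variances still differ; correlation PCA prevents high-variance layers from
dominating by scale alone — a covariance option exists). Eigenvalues
$\lambda_k$ give contribution rates $\alpha_k = 100\lambda_k/\sum\lambda$;
the smallest $N$ with cumulative contribution $\ge$ 85 % is retained, and

$$ I_{EV} = \sum_{k \le N} \frac{\alpha_k}{100} F_k $$

where $F_k$ are the component score surfaces. Because an $\alpha$-weighted
sum is sensitive to the arbitrary sign of each eigenvector, every
component is flipped so its loadings sum to a non-negative value. This
makes the EVI reproducible across eigen solvers (verified in the tests
against an independent SVD route) and orients components "with" the bulk
of the indicators; the convention is recorded on the fitted object. Any
positive rescaling of the $\alpha_k$ would only rescale the EVI and leave
the class ordering unchanged.

Grading uses exact Fisher–Jenks dynamic programming on the run-length
collapsed sorted values (ties are never split), minimizing the total
within-class sum of squared deviations; above 50,000 cells the optimizer
runs on a uniform sample and all cells are then assigned by the resulting
breaks. Class 1 is the slightest vulnerability, class 5 the most extreme.

## Spatial autocorrelation

Moran's I uses binary rook contiguity by default (queen available).
Analysis is meant to run on aggregated cells — `aggregate_blocks()` with a
mean reducer moves, e.g., a 300 m surface onto 900 m analysis cells — so
that the statistic is not dominated by within-neighborhood micro-structure.
Inference is by random relabeling of the values over the cells, two-sided:
$p = (\#\{|I^*| \ge |I|\} + 1)/(B + 1)$.

The local statistic is implemented exactly in its binary-weight form
$I_i = (x_i - \bar{x})\, \sum_j w_{ij} (x_j - \bar{x}) / s^2$ with
$s^2 = \sum_i (x_i-\bar{x})^2/n$, so the additivity identity
$\sum_i I_i = S_0 \cdot I$ holds and is tested numerically. A
row-standardized variant (neighbor means, GeoDa-style) is available behind
a flag; the identity then no longer applies. Per-cell significance uses
conditional permutation — cell $i$'s value is held fixed and its neighbor
values are drawn without replacement from the remaining cells — and
significant cells are classified HH/HL/LH/LL by the sign pattern of the
cell's own deviation and its neighbors' mean deviation, with
non-significant cells labeled NN at $\alpha = 0.05$.

## Geographical detector

The factor detector is the pure variance ratio
$q = 1 - \sum_h N_h \sigma_h^2 / (N \sigma^2)$ with *population* variances
in numerator and denominator (sample variances would cancel
inconsistently across strata of unequal size). Continuous drivers are
discretized with the same Jenks engine (five strata by default; quantiles
available); land use enters with its native categories. Significance
comes from the standard noncentral-F transformation of q, or from
permutation of the stratum labels.

The interaction detector overlays two stratifications (Cartesian pairs
present in the data). Because the overlay refines both partitions, the
pooled within-stratum variance cannot increase, so $q_{12} \ge
\max(q_1, q_2)$ always — a property the tests verify on random scenes.
Interactions are categorized with an independence tolerance of
$|q_{12} - (q_1 + q_2)| \le 10^{-6}$; exact additivity essentially never
occurs on real data, so observed interactions fall into the enhancement
or weakening classes. Risk and ecological detector variants are out of
scope.

## CA-Markov forecasting

`transition_matrix()` tallies cell transitions between two epochs into an
area matrix $A_{ij}$ (km²) and row-stochastic probabilities
$P_{ij} = A_{ij} / \sum_j A_{ij}$; fully persistent classes are
representable ($P_{ii} = 1$). `markov_project()` propagates per-class
areas, conserving the total.

The CA stage needs per-class suitability surfaces; published workflows
typically delegate this to a GIS "suitability image set" without a recipe,
so the construction here is explicit and configurable: suitability of
class $c$ at a cell is the frequency of $c$ in a 5×5 neighborhood
(IDRISI's standard contiguity filter size), optionally blended 50/50 with
the closeness of the cell's EVI to class $c$'s interval midpoint. With the
blend off the per-class surfaces partition unity at every cell.

`ca_simulate()` converts Markov demand into integer cell counts by
largest-remainder rounding per source class, splits each demand evenly
across the cycles (5 by default), and in each cycle converts the
highest-suitability source cells, recomputing suitability from the
evolving map. Ties break by a seeded random jitter, so a seed fixes the
map exactly; converted cells are frozen for the remainder of the run so a
cell takes at most one Markov step per simulated interval. Demands that
exceed the available source cells are clipped with a warning. Achieved
class areas land within 1 % of the Markov projection (tested at 128×128
for 1 and 5 cycles), and validation against a reference map uses
$\kappa = (p_0 - p_c)/(1 - p_c)$.

## The synthetic study region

Because studies of this kind rarely deposit their rasters, the generator
is a first-class module with recorded ground truth:

* `gaussian_field()` — stationary zero-mean fields by circular FFT
  convolution of white noise with a Gaussian kernel (unit-L2 kernel keeps
  expected variance 1); correlation length 0 returns white noise.
* `synth_indicator_stack()` — 13 layers sharing one latent vulnerability
  field with per-layer loadings drawn around 0.75 (negative-polarity
  layers load negatively, so standardization re-aligns them), plus
  independent spatially correlated noise. The land-use layer is cut from
  the latent field, which couples category and vulnerability.
* `synth_known_evi_scene()` — the same stack plus a recorded positive
  linear combination of the standardized layers, the recovery target for
  the EVI (the acceptance experiments require $|r| > 0.9$ at 64×64).
* `synth_class_series()` — epoch-to-epoch class dynamics from a known
  row-stochastic matrix. The per-cell draw uses a spatially correlated
  field (correlation length 2 cells) rank-transformed *within each source
  class*, a stratified scheme under which realized transition frequencies
  match the generating row to within rounding while transitions still
  form patches. This makes transition recovery at 128×128 limited only by
  rounding rather than by spatial sampling noise.
* `synth_zones()` — contiguous Voronoi districts for zonal reporting.

In the orchestrated pipeline the latent field evolves across epochs as an
AR(1) process with coefficient 0.97, reflecting the near-stable
decade-scale dynamics such assessments report: class maps persist
strongly between epochs, and the CA-Markov validation lands in the
"average reliability" band of the conventional kappa scale. All
generators are pure functions of their seed.

What the generator does **not** emulate: real covariance among specific
indicators (the joint distribution is a free modelling choice, recorded in
the truth object rather than asserted as realistic), climate-station
interpolation, imagery-derived NDVI, Fragstats metrics, or any actual
geography. Passing tests therefore demonstrate algorithmic correctness
and statistical calibration on landscapes with the assumed structure —
not fidelity to any particular study area.

## Numerical choices and degenerate inputs

* Jenks: exact DP below 50,000 values; run-length collapse keeps tied
  values together and avoids the floating-point drift of name-based
  tabulation; fewer distinct values than classes is an error.
* Majority aggregation ties break to the smallest code; trailing partial
  blocks aggregate over the cells present instead of shrinking the area;
  all-masked blocks stay masked.
* Constant layers: standardization and both Moran statistics raise
  zero-variance errors; PCA warns and retains zero eigenvalues at the
  tail.
* Permutation p-values are pseudo p-values bounded below by
  $1/(B+1)$; B defaults to 999 and the pipeline refuses $B < 99$.
* Moran weights exclude masked cells entirely; isolated cells get a local
  I of 0 and can only be NN.
* The interaction overlay warns on singleton strata rather than failing;
  a saturated stratification ($k = n$) makes the F test undefined and is
  an error.

## Problem sizes

The test suite exercises 64×64 scenes for EVI recovery and the pipeline,
128×128 for CA-Markov recovery, 16×16 with 200 replicates for permutation
calibration, and brute-force oracles (double-sum Moran, exhaustive Jenks,
group-by q) on grids of at most a few hundred cells — sizes at which the
oracles are exact and the full suite stays fast. The acceptance script
uses the same sizes.

## Limitations

* File I/O is single-band ESRI ASCII text; multi-band stacks persist as
  one file per layer. GeoTIFF is not read or written.
* The suitability construction is a documented stand-in for proprietary
  multi-criteria workflows; the blend ratio is exposed rather than fixed.
* The fragmentation index is a patch-density surrogate, not a landscape
  metrics suite.
* No scenario conditioning in the forecast: the transition matrix is
  assumed stationary one step ahead.
* The q statistic's noncentral-F p-value relies on the standard
  large-sample transformation; for small strata the permutation method is
  the safer choice.
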