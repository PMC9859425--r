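# ecovuln

Raster-based ecological vulnerability assessment for regional planning:
build a **sensitivity–resilience–pressure (SRP)** indicator stack, weight it
into an **ecological vulnerability index (EVI)** with principal component
analysis, grade the surface into five vulnerability levels with Jenks
natural breaks, quantify spatial clustering with **global and local Moran's
I (LISA)**, attribute drivers with the **geographical-detector q-statistic**,
and forecast future vulnerability class maps with a **CA-Markov** model
validated by the Kappa coefficient.

The package targets analysts who assess urban or regional ecological
vulnerability from co-registered indicator rasters (terrain, climate,
vegetation, socio-economic pressure) and need the whole chain — from layer
standardization to a forecast map — reproducible in one scripted run. Since
such studies rarely deposit their rasters, `ecovuln` ships a seeded
synthetic-landscape generator that produces spatially autocorrelated
indicator stacks, clumped land-use maps, district partitions and
multi-epoch class series with recorded ground truth, so every stage can be
exercised and verified end to end.

## The model

**Standardization.** Each indicator layer `a` is rescaled by extreme
differences, respecting its polarity: positive indicators (vulnerability
rises with the value) use `A = (a − a_min)/(a_max − a_min)`; negative
indicators (mean annual temperature, precipitation, NDVI, biological
abundance) use `A = (a_max − a)/(a_max − a_min)`. Land use is a categorical
variable scored 1–6 (waters 1, woodland 2, grassland 3, cropland 4,
construction land 5, bare land 6) and then treated as positive.

**EVI.** A PCA of the standardized stack gives components
`F_k = a_1k X_1 + … + a_pk X_p` with contribution rates
`α_k = 100·λ_k/Σλ`. The smallest N whose cumulative contribution reaches
85 % is retained and

```
I_EV = α_1 F_1 + α_2 F_2 + … + α_N F_N
```

with the `α_k` as proportions. Higher `I_EV` means a more vulnerable
ecosystem. The surface is graded into five levels (slight, light, medium,
heavy, extreme) by exact Fisher–Jenks optimization.

**Spatial structure.** Global Moran's I with binary contiguity weights
`W_ij`,

```
I = n/S0 · ΣΣ W_ij (x_i − x̄)(x_j − x̄) / Σ (x_i − x̄)²
```

with permutation inference, and the local decomposition
`I_i = (x_i − x̄)/s² · Σ_j w_ij (x_j − x̄)` whose significant cells are
labeled HH / HL / LH / LL (others NN).

**Drivers.** The geographical-detector factor statistic
`q = 1 − Σ_h N_h σ_h² / (N σ²)` measures the share of the EVI's spatial
variance explained by a stratified factor; the interaction detector
computes q on the overlay of two stratifications and classifies the pair
(bifactor enhance, nonlinear enhance, independent, weakened).

**Forecast.** A Markov chain estimated from two class maps supplies
per-class transition demand (`S_{t+1} = Pᵀ S_t`); a cellular automaton
allocates that demand over `n` cycles to the cells with the highest
destination-class suitability (neighborhood frequency under a 5×5
contiguity filter, optionally blended with EVI proximity). Agreement with a
reference map is scored by `Kappa = (p0 − pc)/(1 − pc)`.

## Worked example

```r
library(ecovuln)

scene <- synth_known_evi_scene(64, 64, seed = 1)   # stack + known composite
pca   <- fit_pca(scene$stack)
print(pca)
#> <eco_pca: 13 components (correlation matrix)>
#>     eigenvalue contribution cumulative
#> PC1      9.911       76.240     76.240
#> PC2      0.531        4.082     80.323
#> PC3      0.414        3.188     83.511
#> PC4      0.397        3.052     86.562
#> ...

n   <- select_components(pca, threshold = 85)      # -> 4
evi <- compute_evi(pca, n)
round(evi_summary(evi), 3)
#>   mean    min    max
#>  0.000 -5.064  6.020

classes <- classify_natural_breaks(evi)            # five Jenks levels
summary(classes)
#>  slight   light  medium   heavy extreme
#>     290    1017    1190    1008     591

agg <- aggregate_blocks(evi, 3, "mean")            # 900 m analysis cells
W   <- build_weights(agg, "rook")
global_morans_i(agg, W, permutations = 999, seed = 1)
#> Global Moran's I = 0.9566 (expected -0.0021 under the null)
#>   n = 484, S0 = 1848, permutation p = 0.001 (999 permutations)

strata <- discretize_factor(scene$stack[["X7"]]$grid, k = 5)  # NDVI layer
factor_q(evi, strata)
#> GeoDetector q = 0.5782 (n = 4096, k = 5 strata), p = 7.455e-10 [noncentral_f]
```

The PCA table reads like a standard eigen report: the first component
carries 76 % of the stack's correlation-matrix variance (the layers share
one latent vulnerability field by construction), four components pass the
85 % rule, and the EVI built from them correlates > 0.98 with the scene's
recorded composite. The aggregated EVI surface is strongly clustered
(I = 0.96 against an expectation of −0.002), and stratified NDVI alone
explains 58 % of its spatial variance.

The full chain — synthesis, standardization, EVI, LISA maps, detector
tables, CA-Markov forecast, and a report bundle of CSV/ASCII-grid outputs —
runs from one configuration:

```r
res <- run_pipeline(list(rows = 64, cols = 64, seed = 1, out_dir = "bundle"))
print(res)
```

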