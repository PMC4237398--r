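---
title: "Methods: fragmentation indices, change scenarios, and spatial-error regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragmentation indices, change scenarios, and spatial-error regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragscape)
```

This vignette records the models implemented by fragscape, the
assumptions and numerical choices behind them, and what the synthetic
generator does and does not establish.

## Rasters and geometry

Grids are plain matrices in map orientation (row 1 = north), with a cell
size in meters, a top-left origin in projected coordinates, and an
explicit nodata code. Pixel (r, c) has its center at
origin + ((c − 0.5)·h, −(r − 0.5)·h) for cell size h; all distance
computations are center-to-center. Nodata pixels are not landscape: they
are excluded from the total area A_T that normalizes LPI and ED. Two
grids may interact only when aligned (same shape, cell size, origin) —
reprojection and resampling are out of scope. I/O is the ESRI ASCII grid
format; a file that does not declare its cell size or nodata value is
rejected rather than guessed at. Class legends are mapped to the analysis
vocabulary (urban, high-density urban, forest, wetland, pasture,
agriculture, other) through a user-supplied two-column reclassification
table; high-density urban is a subclass counted inside urban by every
operation.

## Patch metrics

Patches are maximal connected components of the focal class under
8-connectivity by default (the FRAGSTATS rule; 4-connectivity is a flag).
Edge, by contrast, is always counted on 4-neighbour pixel faces of length
h: a diagonal adjacency has no physical boundary. The four class indices
are mean patch area AREA_MN (ha), largest patch index LPI (% of A_T),
edge density ED (m per ha of landscape), and the edge-to-area ratio
EDGE_AREA.

Two conventions deserve comment:

* **Boundary policy.** Whether faces against the grid border or nodata
  count as edge is not standardized across studies. The default here is
  `exclude` (conservative: only faces against non-focal land are edge);
  `include` is available and tested. Island-wide values can differ
  noticeably between the policies when a class hugs the coastline.
* **EDGE_AREA units.** The ratio is often printed as m m⁻², but values
  reported for multi-hectare mean patches (hundreds, not hundredths)
  are only consistent with meters of edge per *hectare* of focal area.
  The implementation computes Σe/A with the focal-area unit configurable
  and defaulting to hectares, and records the unit in its output.

A class with no patches yields flagged `NA` indices, never zeros — a zero
mean patch area would silently corrupt the downstream regressions.

## Change scenarios

Comparing the forest masks of two dates partitions land pixels into
unchanged forest (F_F), deforested, reforested, and never-forest. The
deforestation-only scenario keeps F_F alone (the later year with
reforested sites eliminated); the reforestation-only scenario takes the
union of both years' forest (no deforestation occurred). Scenario
landscapes carry a single background class, to which focal metrics are
invariant. Masking the union of both years' urban cover *removes* those
pixels from the landscape (A_T shrinks) rather than recoloring them, so
forest metrics are computed "outside urban areas"; a flag restores the
recoloring behaviour.

The mean distance of a change category to unchanged forest is the
average, over category pixels, of the exact Euclidean center-to-center
distance to the nearest F_F pixel (a Felzenszwalb–Huttenlocher distance
transform; category pixels are never themselves F_F, so distances are
positive). Whether the original workflow used Euclidean or chain
distance is unstated; Euclidean matches the GIS tooling cited for the
other distance surfaces, and only ratio arithmetic between the two
categories is treated as reproducible.

## Grid tiling and the cell table

The landscape is tiled into non-overlapping square cells anchored at the
origin (default 100 × 100 pixels = 3 km at 30 m). Partial cells at the
right/bottom edges are retained, flagged, and subjected to the same
filter as full cells: a cell with fewer than 2,500 land pixels (25% of a
full cell) is discarded. Each retained cell is summarized as its own
landscape (A_T = the cell's land area), with per-class indices per year,
covariate means and standard deviations over land pixels, and signed
pixel-count increments ΔN per class between the first and last year —
increments are pixel counts, not areas, matching the scale on which the
published increment regressions are stated. "Distance to urban centers"
is implemented as the exact distance to any urban pixel of the reference
year's map (the cited GIS workflow), reported in km; slope may be
supplied or derived from elevation by the Horn 8-neighbour gradient.

## The spatial error model

The regression is y = Xβ + ε with spatially correlated error
ε = λWε + ξ, ξ ~ N(0, σ²I), on row-standardized k-nearest-neighbour
weights (k = 8 by default; ties broken deterministically by lowest
index). Writing A(λ) = I − λW, the model is estimated by profiling the
likelihood in λ: for fixed λ, GLS is OLS on the transformed data
(Ay, AX), and the concentrated log-likelihood is
ℓ(λ) = c − (n/2)·log(RSS(λ)/n) + Σᵢ Re log(1 − λωᵢ) over the eigenvalues
ωᵢ of W (complex pairs contribute their conjugate-symmetric real part).
λ is maximized by Brent search on the stationary interval
(1/min Re ω + 10⁻⁴, 1/max Re ω − 10⁻⁴) to tolerance 10⁻⁸. Standard
errors for β come from σ̂²(X'A'AX)⁻¹; the SE of λ̂ from the curvature of
the profile likelihood. AIC counts ncol(X) + 2 free parameters (λ and
σ²). Significance is reported with the two-star convention (p < 0.01,
p < 0.05), asymptotic z-tests, and no multiple-testing correction,
matching the reporting style of the original tables.

Three cross-checks substitute for an external estimator (no spatial
regression package is assumed available): exact reduction to OLS at
λ = 0, agreement of the optimizer with a fine grid scan of the profile
likelihood, and parameter recovery on data simulated from the generating
model (the generator inverts the model: y = Xβ + (I − λW)⁻¹ξ).

A response that an intercept-only design fits exactly (zero residual
variance, e.g. a constant increment) short-circuits the optimizer and is
returned as a flagged degenerate fit.

Term retention is exhaustive minimum-AIC search over candidate subsets
(at most 12 candidates; first- and second-order terms are independent
candidates, since the published models retain e.g. D² without D). The
intercept itself is searchable, as some published mean-patch-area models
carry no intercept. The increment-on-area-change models regress each
index increment on the class increments (and mean distance to urban)
with the same machinery; whether the original increment fits were
spatial is unstated, so the spatial route is the default and an
ordinary fit is one flag away (λ fixed at 0 via the OLS reduction).

## Peaks and shift rates

A fitted response b₁x + b₂x² has its extremum at −b₁/(2b₂) (a maximum
iff b₂ < 0). Peak *locations* are quoted at one decimal, and shift rates
are computed from the rounded locations by default so that published
rates reproduce exactly from published locations; an unrounded mode
exists. The relative rate divides the absolute annual shift by the
earlier location. Predicted curves evaluate the trend Xβ̂ along one
predictor with all other terms at their sample means.

One caveat is structural: vertex locations are comparable across years
only when both years carry the same functional form. The pipeline's peak
report therefore fits dedicated intercept + D + D² spatial-error models
per response and year, while the AIC-selected fits feed the coefficient
and slope-extrema reports. A pure-quadratic model (no first-order term)
has its extremum at 0 and is reported as such, not guessed; responses
whose published form lacks D² are reported as having no interior peak.

## The synthetic generator

The generator exists so that every stage of the pipeline is testable
without the original (undistributed) maps. Its defaults state a world
loosely modeled on the study island around 1991–2000; they are fixed
choices, not tuning knobs.

* **Landscape** (`generate_landscape`): modified random clusters — a
  Bernoulli percolation mask at fixed subcritical fill 0.35, drawn at a
  block scale that grows with `clumpiness`, labeled into 4-connected
  clusters, assigned to classes against pixel quotas, and grown outward
  by multi-source BFS so patches have true interiors. Quotas are
  enforced in seed units because growth hands each cluster territory
  proportional to its seed count; realized class proportions land within
  about one percentage point of the request at default clumpiness on
  grids of 200 × 200 and larger (the spread grows with clumpiness, as
  fewer, larger clusters carry more sampling variance). Class
  proportions default to 40% forest, 12% urban (a quarter of it
  high-density), 30% pasture, 6% agriculture, 4% wetland. Urban cover is
  organized around a small number of nuclei, with a scatter share going
  to the largest clusters anywhere on the map (compact towns). At
  clumpiness 0 the draw is an independent per-pixel multinomial.
  Full growth makes patch scale depend on seed-cluster density, which is
  why clumpiness maps to a block scale (patch area ∝ block²) rather
  than to the fill probability: the block form is what makes patch size
  monotone in the parameter.
* **Change pair** (`generate_change_pair`): deforestation removes 18% of
  first-year forest as contiguous clearings grown from seeds in the
  erosion core (≥ 2 pixels inside the boundary); the default clearing
  size of 12 pixels (~1 ha) places cleared pixels about two pixel-widths
  from remaining forest, the scale of the published deforested-site
  distance (~56 m). Clearings convert per-blob — never per-pixel, which
  would dust the interior with isolated urban cells — 75% to pasture and
  21% to urban, urban-fated clearings being those nearest existing
  development. Reforestation adds ~20% of first-year forest (net +2%) as
  regrowth patches on the forest edge, each advancing outward from an
  edge seed (~30 pixels), the scale of the published reforested-site
  distance (~67 m). Urban growth (8% by default) is sampled with
  probability decaying in distance from sprawl sources, cut off beyond
  three decay lengths; a configurable share founds compact new towns
  anywhere on the land surface. The embedded truth map is exactly what
  `classify_forest_change` returns on the pair.
* **Covariates** (`generate_covariates`): smoothed-noise elevation, Horn
  slope clipped to [0°, 45°], population density as patch-area-weighted
  Gaussian kernels on the largest urban patches over a rural floor of
  10 km⁻², and the exact distance-to-urban surface.
* **SEM data** (`generate_sem_data`): an exact draw from the model on a
  lattice (when n is a perfect square) or uniform random points.

`simulate_sprawl_island()` composes these into the end-to-end scenario:
a monocentric island observed at a reference date and two later dates,
with the development reach lengthening between epochs (1.2 km then
2 km — accelerating sprawl) and new towns founded far from the core.
Because the distance covariate is frozen at the reference date, later
towns contribute compact, low edge-to-area urban at large distances;
scattered sprawl contributes fragmented urban at intermediate
distances. That geometry is what makes the urban edge-to-area ratio
rise and then fall along the distance axis and its peak move outward —
the sprawl signature the pipeline is designed to detect. The scenario's
specific settings (single core, 6% initial urban, 40% of growth in new
towns of ~300 pixels) were chosen for that geometry and fixed.

What a green synthetic test establishes: the estimators recover known
parameters from their own generating model; the metric code agrees with
brute-force oracles; the pipeline's qualitative conclusions follow from
a world built with the mechanisms the study describes. What it does not
establish: agreement with the original island-wide index values or
regression coefficients, which require the source maps; those numbers
enter only as shipped published tables from which worked-example
arithmetic (peak locations, shift rates, scenario percentage changes) is
recomputed.

## Known limitations

* ESRI ASCII is the only raster format; GeoTIFF input must be converted
  first (no GeoTIFF reader is assumed available).
* The SEM's λ standard error is profile-curvature based, not from the
  full information matrix; λ̂ itself and β inference are unaffected.
* Cell-level EDGE_AREA is volatile in cells whose focal class is a tiny
  sliver of a patch that mostly lies elsewhere; with few cells this can
  destabilize fitted quadratics. The pipeline mitigates it by fixing the
  peak-fit functional form, not by censoring cells.
* Exhaustive AIC search is exponential in the candidate count and capped
  at 12 terms.
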