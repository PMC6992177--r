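---
title: "Methods: wetland vulnerability indices over hydrologically delineated marsh units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wetland vulnerability indices over hydrologically delineated marsh units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshwvi)
```

## The model

A coastal marsh complex is treated as a mosaic of *conceptual marsh units*:
polygons bounded by elevation ridge lines, each draining through a single
point. Per unit, ten indicator layers — five chronic (elevation ELEVA,
tidal range TIDER, shoreline change SHORE, unvegetated-to-vegetated ratio
UVVR, residence time RESID) and five episodic (sediment-supply change
SEDIM, salinity change SALIN, salinity exposure EXSAL, marsh condition
change CONDC, contaminant exposure SCORR) — are summarized, oriented so
larger means more vulnerable, and cut into four equal-occupancy categories
encoded 0, 1/3, 2/3, 1. The wetland vulnerability index of a unit is the
arithmetic mean of its ranked indicators; chronic-only (WVIC) and
episodic-only (WVIE) means are reported alongside, and a per-unit rank
dispersion (population SD of the ranks) distinguishes unanimous from
conflicted vulnerability.

The central assumptions are (i) *relative* vulnerability is meaningful:
ranks compare units within the study domain, not against absolute critical
values; (ii) equal weights: no indicator is privileged, a choice the
principal-component analysis is used to scrutinize (if one or two
components dominated the variance, equal weighting would be suspect);
(iii) the indicator layers are exogenous inputs — their production
(hydrodynamic modeling, remote sensing, contaminant scoring) is outside
the package.

## Delineation rules

Flow routing is D8: each cell drains to the neighbor maximizing
drop/distance, diagonals at distance `cellsize * sqrt(2)`. The choices a
D8 router must make, fixed here deterministically:

* **Ties** between equally steep neighbors break by the fixed order E, SE,
  S, SW, W, NW, N, NE.
* **Flats** (no strictly lower neighbor) that can reach a lower cell
  through a run of equal-elevation neighbors drain by breadth-first
  gradient toward the nearest draining cell of the flat; this matters
  because near-flat marsh platforms would otherwise shatter into
  single-cell basins.
* **Closed minima** — including each cell of a closed flat and boundary
  cells with no lower in-grid neighbor — are sinks. Nodata is
  impermeable; descent cannot cross it or leave the raster, so low edge
  cells become edge sinks.

Basins are labeled by terminal sink, polygonized with rook (shared-edge)
contiguity — a basin connected only through cell corners splits, the part
without the sink taking its lowest cell as drainage point. Units below the
minimum area (default 5,000 m²) merge iteratively, strictly smallest
first, into the adjacent unit with the nearest centroid, with all
attributes recomputed after every merge; a rook-connected cluster of
sub-threshold units with no large neighbor dissolves into one unit with
provenance `"aggregated"`. Ties (equal areas, equal centroid distances)
resolve to the lowest unit id, making the whole procedure reproducible
bit-for-bit. An isolated sub-threshold island with no neighbors at all is
left as-is: there is nothing to merge it into.

## Ranking conventions

Percentile classification sorts the non-missing oriented values ascending,
stably (value ties break by unit id), and cuts at ordinal quartiles; with
`n = 4q + r` the first `r` categories take `q + 1` members. This preserves
exact equal occupancy — the stated purpose of percentile ranking — at the
cost that tied values may straddle a category edge. Category thresholds
are reported back on the raw scale as contiguous bins covering the
observed range (decreasing bins for inverted indicators, as such tables
are conventionally printed).

The numeric encoding 0, 1/3, 2/3, 1 makes the index attain exactly 0 and
1 and splits as WVI = (WVIC + WVIE)/2 whenever all ten indicators are
present. Missing indicator values are carried, never imputed: the index
divisor is the per-unit count of available indicators, so a unit without
(say) shoreline data keeps a defined WVI, with `n_used` recording the
reduced support.

## Multivariate analysis conventions

Correlations, z-normalization and PCA all use the sample (n−1) standard
deviation. The pipeline computes them on the *ranked* values (the
vulnerability quantities themselves); `pca_indicators(..., scale = TRUE)`
decomposes the correlation matrix, appropriate for incommensurate units,
while `scale = FALSE` decomposes the covariance for data already on a
common scale — the package exposes both because either convention is
defensible and they answer slightly different questions. Loading signs
follow a deterministic convention (largest-magnitude loading positive).
Component retention offers the three standard rules: the scree deflection
point is implemented as the index of the maximum second difference of the
eigenvalue sequence; the cumulative rule takes the smallest count whose
variance fraction exceeds 85 %; the above-mean rule counts eigenvalues
strictly greater than the mean (an all-equal spectrum retains zero, with
a warning).

Clustering fits full-covariance Gaussian mixtures by EM, written in the
package so that restart policy, regularization and the per-iteration
log-likelihood trace are all inspectable: 10 seeded restarts initialized
from random rows with nearest-center hard assignment, convergence at a
relative log-likelihood change below 1e−8 or 500 iterations, and a ridge
of `1e-6 * trace(S)/d` on every M-step covariance. A restart whose
components degenerate is abandoned and reseeded. The number of components
minimizes `BIC = p ln(n) − 2 lnL` with
`p = (K−1) + Kd + Kd(d+1)/2` free parameters. Cluster departure profiles
report each cluster's mean z-score per indicator (so +1 is one standard
deviation above the domain mean) and their sum, a scalar more/less
vulnerable-than-average summary; size-weighted departures cancel exactly
by construction.

One consequence of the full-covariance penalty worth knowing: with d = 10
indicators the penalty per extra component is 76 ln n, so a mixture of a
few hundred units cannot statistically support more than one component
even when mild structure exists. Cluster-recovery experiments in the
package therefore use low-dimensional mixtures (d = 3, components 8 SD
apart), where the BIC answers the question being asked; the 10-indicator
tables still exercise the fitting path.

## Hotspots and transects

Seeds are units with WVI strictly above mean + 1 SD (the multiplier is
configurable). Buffers (default 1,000 m) are drawn around seed *geometry*,
overlapping buffers dissolve, and membership is by member *centroid*
within the buffer — reconciling the two natural readings of
"units within 1 km"; a unit reachable from two zones joins the nearer
seed, keeping membership disjoint. Zones survive only with more than one
member and at least 2 km² total area (defaults; the synthetic pipeline
scene applies the area rule as a fraction of its domain because a
desk-scale scene is far smaller than 2 km²). Transects order units by the
distance along a polyline at first entry, computed exactly from
segment/cell-rectangle intersections.

## What the synthetic generators emulate

* `generate_dem()` builds inverted-Gaussian-bowl surfaces whose
  ridge lines separate known attraction basins, plus a small deterministic
  slope toward the nearest center (so far-field cells are never exactly
  flat) and optional noise. It emulates ridge-bounded drainage structure —
  not channels, ditches, levees or tidal creeks.
* `generate_unit_geometries()` tessellates a rectangle into contiguous
  Voronoi-style units on a fine grid; areas sum exactly to the rectangle.
* `generate_indicator_table()` draws latent Gaussians with a target
  correlation (default: the package's built-in signed structure with a
  strong TIDER–RESID pair near 0.93, negative SEDIM pairs, a positive
  ELEVA–UVVR pair, near-zero SHORE), pinned to the *sample* correlation
  (`MASS::mvrnorm(empirical = TRUE)`) because the generator's contract is
  to reproduce that structure, then maps margins monotonically onto each
  indicator's published min–max range through a damped probit
  (`pnorm(z/2)`), giving bounded bell-shaped margins with Pearson
  attenuation below 0.01. Monotone margins mean every rank-based
  downstream statistic is independent of the marginal choice. An optional
  monotone along-estuary gradient on selected indicators emulates
  longitudinal estuarine structure.
* `generate_clustered_table()` draws labeled Gaussian components; the
  default sizes (51, 18, 31) mirror a majority/minority three-regime
  share pattern.

What passing tests on these generators shows — and does not. They verify
the *algorithms*: exact basin recovery away from ridges, equal-occupancy
ranking, index identities, mixture recovery, the hotspot rule. They do not
validate the index against real marsh outcomes: real indicator layers
have spatial autocorrelation, heavy tails, shared measurement error and
missingness patterns that the copula draws do not reproduce.

## Numerical choices and degenerate inputs

* All-nodata rasters, NaN cells, non-positive cell sizes, zero-variance
  columns (named in the error), non-PSD correlation targets (with a
  pointer to `nearest_psd_correlation()`), undefined UVVR (zero vegetated
  area), and under-sized clusters all fail loudly or flag explicitly —
  never silently zero.
* Ranking requires at least as many non-missing values as categories.
* The EM log-likelihood is evaluated through Cholesky factorizations; the
  covariance ridge keeps them defined. The trace is monotone up to
  floating-point noise (tests allow a relative slack of 1e−8).
* Problem sizes in the test-suite and acceptance scenes (grids up to
  120 × 90 at 5 m, 20-basin scenes, n = 2000 copula draws, 20-seed
  recovery experiments at n = 300) were chosen as the smallest sizes at
  which each statistical property is informative.

## Known limitations

* D8 single-direction routing only; no D-infinity or multiple-flow
  apportionment, no channel burning, and geographic (degree-unit) rasters
  are out of scope — grids must be planar in meters.
* Zonal statistics use cell-center membership without areal weighting, so
  very coarse layers over small units lose precision.
* The hotspot buffer is computed on grid cell geometry; at 1 m resolution
  this is exact to the cell, not to survey geometry.
* The GMM assumes full-covariance Gaussian components on ranked values,
  which are discrete (four levels); with many units the normal
  approximation is serviceable, with few it is not, and BIC then prefers
  K = 1.
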