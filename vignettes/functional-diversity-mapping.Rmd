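---
title: "Mapping forest functional diversity from trait rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping forest functional diversity from trait rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitdiv)
```

## The method

`traitdiv` maps the functional diversity of a forest canopy directly from
remotely sensed plant traits, without identifying species or individual
trees. Each pixel of a trait raster is treated as one measurement of a
community member: a point in a three-dimensional trait space whose axes are
normalized functional traits. Two trait families are supported, each with
three traits:

* **morphological** — canopy height (CH, m), plant area index (PAI,
  projected plant area per ground area) and foliage height diversity (FHD,
  the Shannon entropy of the vertical plant-area profile), typically
  retrieved from airborne laser scanning;
* **physiological** — relative leaf chlorophyll (CHL), carotenoids (CAR)
  and equivalent water thickness (EWT), retrieved from imaging
  spectroscopy via band-ratio indices.

For every focal pixel, all forest pixels whose centres fall within a
circular window of radius $r$ are mapped into trait space, and three
complementary indices of the resulting point cloud are computed:

* **functional richness** (FRic): the volume of the 3-D convex hull — the
  extent of the occupied community niche. Because traits are normalized to
  $[0,1]$, the hull volume lies in $[0,1]$ as well.
* **functional divergence** (FDiv): with $dG_i$ the Euclidean distance of
  point $i$ from the centre of gravity, $\overline{dG}$ their mean and
  $\Delta|d| = \tfrac1S\sum_i |dG_i - \overline{dG}|$,
  $$\mathrm{FDiv} = \frac{\overline{dG}}{\Delta|d| + \overline{dG}}.$$
  FDiv equals 1 exactly when all points are equidistant from the centre.
* **functional evenness** (FEve): from the Euclidean minimum spanning tree
  (Prim's algorithm) with branch lengths $EW_l$ and
  $PEW_l = EW_l / \sum_l EW_l$,
  $$\mathrm{FEve} = \frac{\sum_l \min\!\big(PEW_l, \tfrac{1}{S-1}\big)
    - \tfrac{1}{S-1}}{1 - \tfrac{1}{S-1}}.$$

Every pixel has weight 1: no abundance weighting is applied, because each
pixel already is one unit of observed canopy. Repeating the computation
over a schedule of radii (by default 6–1020 m in 6 m steps, i.e. 170
extents with areas from 113 m² to $3.27\times10^6$ m²) yields
diversity–area curves analogous to species–area relationships, which the
package summarises with two standard fits: a power law
$V = c\,A^z$ (ordinary least squares of $\ln V$ on $\ln A$) and a
logarithmic model $V = a + b \ln A$.

Two reference arrangements put the observed curves in context:

* the **shuffle null model** permutes the trait *triplets* uniformly over
  the forest pixel positions. The multiset of triplets, hence every trait
  histogram and every inter-trait correlation, is exactly preserved, while
  all spatial structure is destroyed;
* the **maximal under-dispersion model** replaces each focal pixel's
  geographic neighbourhood of size $N$ with its $N$ nearest neighbours in
  trait space — the arrangement that would result from the strongest
  possible environmental filtering.

If observed small-window richness lies well below the shuffle null, trait
convergence dominates (co-occurring canopies are more similar than
random); the under-dispersion curve marks the lower bound of that
behaviour.

## From raw inputs to trait stacks

The trait module covers the steps from sensor-level products to the
normalized stack:

* `compute_fhd()` applies $-\sum_i p_i \ln p_i$ to per-pixel vertical
  plant-area profiles. The vertical bin thickness is a free parameter of
  the profile container; it cancels from the proportions $p_i$.
* `chl_index()`, `car_index()` use the three-band pigment model,
  e.g. $\mathrm{CHL} = (1/R_{540-560} - 1/R_{760-800})\,R_{760-800}$,
  where $R_{i-j}$ is the unweighted mean reflectance over the closed
  wavelength window. `ewt_index()` is the simple-ratio water index
  $1 - R_{1193}/R_{1126}$ on the single band nearest each target
  wavelength (within ±10 nm, otherwise an error — silently using a distant
  band would change the physical meaning of the index).
* `aggregate_brightest()` reduces fine blocks (3 × 3 of 2 m pixels to
  6 m) to the mean of the three brightest valid pixels, suppressing
  shadowed pixels whose retrievals are distorted. *Brightness* is defined
  here as the mean 760–800 nm reflectance: the NIR plateau is the part of
  a vegetation spectrum least affected by shadowing; a broadband mean can
  be supplied instead through the `brightness` argument. Index values are
  computed per fine pixel first and aggregated afterwards, keeping the
  aggregation a pure trait-space average.
* `normalize_trait()` performs scene-wide min–max scaling over forest
  pixels. Scene-wide (rather than per flight line) bounds keep relative
  trait differences comparable across the whole map. An optional
  percentile clip (default off) is available for data with extreme
  outliers; it winsorizes before scaling so the bulk of the distribution
  keeps its resolution. Negative raw index values (possible for EWT) are
  handled by this same normalization rather than being clipped earlier.
* `forest_mask()` derives the analysis mask from a canopy height model in
  three steps: mature canopy at CH ≥ 10 m, filling of fully enclosed gaps
  (4-connected holes not touching the raster border, so juvenile patches
  inside the forest are recovered), then intersection with CH ≥ 4 m to
  remove true gaps and understorey. The hole filling is implemented as a
  border flood fill; 4-connectivity is the conservative choice — it fills
  strictly enclosed regions only.

## The synthetic landscape generator

The generator exists so the entire pipeline is testable without any
external data; it is first-class, tested code. `landscape_spec()` fixes
the study conditions: a 200 × 200 pixel scene at 6 m grain (1.2 × 1.2 km,
the working resolution of crown-scale airborne trait maps), Gaussian
random fields with 60 m autocorrelation length (the scale of stands of
similar structure), a cross-trait correlation of $r^2 = 0.7$ between the
first two traits with weaker ($r^2 \approx 0.3$) correlations elsewhere
(the pattern observed between canopy height and foliage height diversity
in temperate mixed forest), a mild cross-scene gradient standing in for an
altitudinal trend, and a handful of 30–90 m disturbance patches with
offset traits emulating juvenile regrowth.

Each trait field is the sum of a smooth component (white noise convolved
with a Gaussian kernel via FFT) and a **nugget**: 10 % of the variance is
spatially unstructured pixel-scale variability. The nugget matters beyond
realism (crown-to-crown contrast and sensor noise): on a perfectly smooth
field, geographically adjacent pixels are *also* each other's nearest
trait-space neighbours, so the observed arrangement would itself be
maximally under-dispersed and the two null models would not be
distinguishable from the data. Cross-trait correlation is imposed by
Cholesky mixing of the standardized fields, which leaves each field's
marginal structure untouched.

The companion generators forward-model the other raw inputs:
`generate_reflectance_cube()` builds a 14-band toy cube in which each
index's absorption window darkens monotonically with its generating trait
(so the spectral indices recover the fields rank-for-rank, which the tests
assert), `generate_chm()` produces canopy heights in a mature-forest range
of 12–55 m with optional clearings and enclosed gaps for mask testing, and
`generate_profile_stack()` draws per-pixel vertical profiles from a
symmetric Dirichlet whose concentration field controls the expected FHD.

What the generator does *not* emulate: real sensor geometry (view-angle
and shadow effects), within-scene co-registration error between the two
trait families, non-Gaussian trait marginals, and ecological structure
beyond second-order statistics (e.g. species mosaics). Passing tests on
synthetic scenes therefore demonstrate the correctness of the computation
and the qualitative null-model behaviour, not quantitative agreement with
any particular forest.

## Numerical choices

* Hull construction snaps coordinates to a $10^{-12}$ grid first, making
  exactly-coplanar neighbourhoods (common on quantised rasters) reliably
  degenerate. Degenerate point sets — fewer than four distinct points, or
  collinear/coplanar configurations — return a richness of **0** with a
  `degenerate` attribute, not an error or missing value: a flat
  neighbourhood is a genuine zero-volume niche. `degenerate_as_na = TRUE`
  switches to the missing-value convention.
* FDiv is undefined when all points coincide ($\overline{dG}=0$) and FEve
  is undefined for $S<3$ (the $S=2$ denominator vanishes) or a zero-length
  tree; both are returned as nodata.
* The MST breaks ties between equal-length candidate edges towards the
  lexicographically smaller (origin, destination) index pair, so results
  are bit-reproducible. The under-dispersion model breaks trait-space
  distance ties towards the smaller flat (column-major) pixel index.
* Window membership is by pixel-centre distance with a closed disc
  (≤ radius). Windows at the forest edge or map edge simply use the masked
  pixels that fall inside the disc; a `min_points` threshold (default 4
  for richness — the smallest S that can enclose volume) marks thinner
  samples nodata.
* Shuffle-null replicate $k$ uses sub-seed `seed + k`, so any single
  replicate can be reproduced in isolation; 50 replicates is the default
  compromise between Monte-Carlo error of the null mean and runtime.
* Power-law fits exclude non-positive curve values with a warning (they
  have no logarithm; they arise from fully degenerate landscapes). The
  `min_area` option restricts either fit's domain, e.g. to areas above
  1 ha where richness–area curves tend to be log-linear.

## Problem sizes

The package's test-suite and acceptance computations run on the generator
defaults (200 × 200 pixels at 6 m) for the null-model comparisons, with
smaller grids (up to 60 × 60) for distributional property checks, window
radii of 12–120 m, 50 shuffle replicates, $10^5$ Monte-Carlo draws for the
hull oracle, and exhaustive spanning-tree enumeration up to $S = 8$. These
sizes were chosen so that each check has clear statistical margins while a
full run of the suite completes in minutes on a single core.

## Known limitations

* Indices are defined for exactly three traits (the trait-space dimension
  is fixed at 3); alternative functional-diversity measures such as Rao's
  quadratic entropy are out of scope.
* The under-dispersion inequalities (sample variance and richness at or
  below the geographic sample's) hold in the mean and almost always per
  pixel, but are not strict theorems: on strongly autocorrelated scenes a
  geographic sample can be near-degenerate and flatter than the
  trait-space ball. The tests allow for that with a small slack.
* Raster I/O is deliberately minimal: ESRI ASCII grids for single bands
  and ENVI BSQ for cubes. Projection metadata is not carried; all
  distances are computed in map units from the pixel size.
* The moving-window engine recomputes every hull independently. This is
  simple and exactly parallel to the per-pixel definition, and is fast in
  the compiled core for desk-scale rasters ($10^4$–$10^5$ pixels), but it
  is not an incremental-hull algorithm and will not scale to national
  mosaics as-is.

## A minimal end-to-end run

```{r example, eval = FALSE}
spec <- landscape_spec(nrow = 100, ncol = 100, seed = 1)
st <- generate_trait_stack(spec)

# per-pixel maps at a 60 m window
map60 <- diversity_map(st, "richness", 60)

# diversity-area curve and fits over 12-120 m
sched <- radius_schedule(12, 120, 12)
curve <- diversity_area_curve(st, "richness", sched)
fit_power_law(curve)
fit_logarithmic(curve)

# null models
null_sh <- null_curve(st, "richness", sched, model = "shuffle",
                      n_replicates = 50, seed = 1)
null_ud <- null_curve(st, "richness", sched, model = "underdispersion",
                      sampling = "grid")
```
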