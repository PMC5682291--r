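# traitdiv

Spatially continuous, taxonomy-free mapping of forest functional
diversity from remotely sensed trait rasters.

Classical functional-diversity assessment needs species identities, plot
inventories and trait databases. When plant traits are instead *measured
per pixel* — canopy structure from airborne laser scanning, leaf
physiology from imaging spectroscopy — every pixel is one community
member, and diversity can be computed directly, continuously in space and
at any spatial scale, with intra-specific variation included for free.
`traitdiv` implements that pipeline for users of high-resolution trait
maps: remote-sensing ecologists, forest scientists, and anyone studying
diversity–area scaling or community assembly from raster data.

## What it computes

Pixels inside a circular window of radius *r* are mapped into a
normalized 3-trait space (morphological CH/PAI/FHD or physiological
CHL/CAR/EWT), and three indices summarise the resulting point cloud of
*S* pixels:

* **Functional richness** — the 3-D convex hull volume of the points:
  the extent of the occupied niche, in [0, 1] for unit-scaled traits.
* **Functional divergence** — with `dG_i` the distance of point *i* to
  the centre of gravity, `dG` their mean, and
  `Δ|d| = Σ|dG_i − dG| / S`:

  ```
  FDiv = dG / (Δ|d| + dG)
  ```

* **Functional evenness** — from the Euclidean minimum spanning tree
  (Prim) with branch lengths `EW_l` and `PEW_l = EW_l / ΣEW`:

  ```
  FEve = ( Σ min(PEW_l, 1/(S−1)) − 1/(S−1) ) / ( 1 − 1/(S−1) )
  ```

A moving window evaluates the indices at every forest pixel; sweeping the
radius schedule (default 6–1020 m in 6 m steps, 170 extents) yields
diversity–area curves with power-law (`V = c·A^z`) and logarithmic
(`V = a + b ln A`) fits. Two null models calibrate the curves: a
trait-triplet **shuffle** (spatial structure destroyed, trait
relationships exactly preserved) and **maximal under-dispersion**
(each window replaced by its trait-space nearest neighbours).

Upstream of the indices, the package derives foliage height diversity
from vertical plant-area profiles (Shannon entropy), chlorophyll,
carotenoid and water indices from reflectance cubes, brightest-pixel
aggregation, scene-wide trait normalization, a CH-based forest mask with
gap filling, and RGB trait composites. A seedable synthetic landscape
generator (correlated Gaussian random fields, gradient, disturbance
patches, toy reflectance forward model) makes the whole pipeline testable
without any external data.

## Worked example

```r
library(traitdiv)

spec  <- landscape_spec(nrow = 100, ncol = 100, seed = 1)
st    <- generate_trait_stack(spec)
st
#> <trait_stack> [CH, FHD, PAI]: 100 x 100 px @ 6 m, 8464 forest pixels

diversity_map(st, "richness", 60)
#> <diversity_map> richness @ r = 60 m: 100 x 100 px, 8464 valid, mean 0.0158

curve <- diversity_area_curve(st, "richness", radius_schedule(12, 96, 12))
round(as.data.frame(curve), 5)
#>   radius_m    area_m2    mean      sd    n
#> 1       12   452.3893 0.00066 0.00043 8464
#> 2       24  1809.5574 0.00297 0.00151 8464
#> 3       36  4071.5041 0.00644 0.00300 8464
#> 4       48  7238.2295 0.01049 0.00469 8464
#> 5       60 11309.7336 0.01576 0.00686 8464
#> 6       72 16286.0163 0.02078 0.00888 8464
#> 7       84 22167.0778 0.02714 0.01130 8464
#> 8       96 28952.9179 0.03330 0.01344 8464

fit_power_law(curve)
#> <scaling_fit> V = 2.447e-06 * A^0.9352  (r2 = 0.9959, n = 8)

null_curve(st, "richness", radius_schedule(12, 24, 12),
           model = "shuffle", n_replicates = 20, seed = 1)[, c(1, 3)]
#>   radius_m    mean
#> 1       12 0.01496
#> 2       24 0.04482
```

Reading the numbers: mean richness grows with window area (more pixels
reach further into trait space), and the shuffled landscape is far richer
at small radii (0.015 vs 0.0007 at 12 m) — on this strongly
autocorrelated synthetic scene, co-occurring pixels are much more similar
than random, i.e. trait convergence.

The moving-window maps, curves and fits are also reachable from a shell
via the thin CLI wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/traitdiv.R", package = "traitdiv"))')" \
    synth --out demo --size 100 --seed 1
```

with subcommands `fhd`, `spectral`, `mask`, `diversity`, `curve`, `fit`,
`null`, `synth` and `run` (YAML-configured full pipeline, see
`?run_pipeline`).

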