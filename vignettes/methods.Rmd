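---
title: "Stepwise juniper distribution modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise juniper distribution modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wepmap)
```

## The procedure and its assumptions

`wepmap` maps evergreen juniper canopy by elimination rather than by a
trained classifier. Every stage is a mask on a shared 1 m lattice, and each
mask can only remove pixels from the previous one, so the final juniper
layer is nested inside tree cover, which is nested inside the canopy-height
mask. The stages are:

1. *Exclusions*: water/cropland from categorical land-cover grids, road
   corridors, and sub-acre municipal ("urban") parcels. These areas are
   never classified.
2. *Canopy*: canopy height at least one foot (0.3048 m), from a LiDAR-derived
   canopy-height model, then an opening plus island removal to drop speckle.
3. *Tree cover*: canopy pixels that are green in summer by both
   NDVI >= 0.1 and EVI >= 1.8 (inclusive thresholds).
4. *Juniper*: tree pixels whose winter (leaf-off) composite NDVI is strictly
   greater than 0.35. The physical assumption doing the work here is that
   deciduous canopies lose their green signal between January 1 and
   February 14 while evergreens keep it.
5. *Staging*: Euclidean distance from the juniper mask assigns encroachment
   (within 50 m) and dispersal/recruitment (50–250 m) rings; everything
   further is intact; exclusions overlay last as their own class.

The chain assumes co-registered inputs in one projected, meter-unit CRS;
geographic (degree) rasters are refused at ingestion. Coarser inputs
(10 m land cover, 10 m winter scenes) are carried to the 1 m lattice by
nearest-neighbour resampling of pixel centers — the mechanism by which a
10 m product becomes a "1 m" layer, and deliberately the simplest one.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `ndvi_tree` | 0.1 | index, inclusive | summer greenness floor for tree cover |
| `evi_tree` | 1.8 | index, inclusive | separates canopy from grass; scale-dependent (digital numbers) |
| `ndvi_juniper` | 0.35 | index, strict > | winter evergreen gate |
| `cloud_max` | 0.10 | fraction, strict < | scene-level cloud cap |
| leaf-off window | Jan 1 – Feb 14 | per year | deciduous leaf-off period |
| `min_height_m` | 0.3048 | m, inclusive | one-foot canopy floor |
| land-cover buffer | 15 | m | collar on water/crop mask |
| urban buffer | 30 | m | collar on sub-acre municipal parcels |
| road widths | 25 / 250 / 30 / reported (default 30) | ft per side | corridor half-widths by category |
| `encroach_buffer_m` | 50 | m | encroachment ring |
| `dispersal_buffer_m` | 200 | m | further dispersal/recruitment ring |
| `open_radius_px` | 1 | px | opening kernel radius (3×3 square) |
| `min_island_px` | 10 | px | smallest surviving 4-connected component |

The tree-cover thresholds are inclusive while the juniper threshold is
strict; the source method states the juniper gate as "greater than" but the
tree gates only as "a threshold of", and the package fixes that reading once
and exposes all values in configuration. EVI uses the standard constant set
G = 2.5, C1 = 6, C2 = 7.5, L = 1; because EVI is not invariant to band
scaling, the 1.8 threshold is only meaningful on the digital-number scale
the imagery is declared in.

## Numerical choices

* **Morphology** uses a square structuring element of side
  `2*radius + 1`, one opening pass, with the lattice zero-padded so that
  pixels outside the grid count as background (the erode/dilate duality then
  holds with 0-padding on the boundary). Kernel shape, pass count and the
  island floor are not dictated by the method's description; these defaults
  are the package's own and are configurable.
* **Distance buffering and staging** use an exact Euclidean distance
  transform between pixel centers. The two staging rings are computed from
  a single transform of the juniper mask: the dispersal/recruitment ring is
  the 50–250 m annulus, which is equivalent to buffering the encroachment
  stage by a further 200 m under Euclidean distance. Ring bounds are
  inclusive on the outer edge. Buffers propagate across excluded pixels (a
  road does not shield the land behind it from seed rain); exclusion is
  overlaid after staging.
* **Compositing** averages each band over the scenes that pass the cloud
  and date gates; cloud handling is scene-level only (per-pixel cloud
  masking is deliberately not applied), and nodata pixels are dropped from
  the mean rather than poisoning it.
* **Zonal assignment** is by pixel-center containment, first polygon wins
  on shared boundaries; no partial-pixel area weighting. Units are clipped
  to the study boundary, and unit percentages are relative to the
  in-boundary unit area. Elevation and juniper-height statistics convert to
  feet at output only (1 ft = 0.3048 m; 1 acre = 4046.8564224 m²).
* **Degenerate inputs**: empty masks buffer to empty; an empty scene list,
  an all-zero reference column, or zero variance of paired differences are
  explicit errors; validation points on excluded or nodata pixels predict
  "other" and are flagged rather than dropped.

## The synthetic landscape

The generator (`landscape_config()` / `generate_landscape()`) emulates the
statistical structure the classifier relies on, not the appearance of real
imagery:

* circular tree crowns grouped into the four juniper configurations —
  lone (isolated single crowns), edge (rows along local roads just outside
  the corridor buffer), groups (fewer than six crowns), stands (more than
  six crowns coalescing into a closed-canopy blob) — plus deciduous
  patches;
* Gaussian per-cover radiometry on a 0–255 digital-number scale, with
  summer indices separating trees from grass and winter NDVI separating
  evergreen (~0.78 at 1 m) from leaf-off deciduous and dormant grass
  (~0.11–0.13);
* the resolution mismatch: winter bands are exact 10×10 block means of the
  latent 1 m radiance. With the default radiometry a satellite cell crosses
  the 0.35 winter threshold near 21% evergreen coverage, so a lone crown
  (at most ~20 m² in a 100 m² cell) cannot be detected while stand
  interiors always are — reproducing the lone < edge ≤ group ≤ stand
  producer's-accuracy ordering as a structural property, not a tuned one;
* two 10 m land-cover products with different legends and a deliberate
  disagreement in water extent, two overlapping canopy-height tiles, a
  seven-scene winter catalog in which one scene fails the date window and
  one the cloud gate, and a parcel fabric with a municipal block of
  sub-acre parcels.

Default object counts (12 lone, 4 edge rows, 10 groups, 6 stands, 8
deciduous patches on a 1,000 m extent) give a sparse working landscape in
which objects keep enough mutual separation that validation-point classes
stay unambiguous. All randomness flows from one seed; identical configs
produce bit-identical bundles.

What the generator does **not** emulate: atmospheric and BRDF effects,
per-pixel clouds and shadows, species-level spectral differences,
phenology beyond the two seasons, terrain-correlated vegetation, and
realistic parcel shapes. Passing tests therefore demonstrate that the
pipeline implements its stated contracts and reproduces the
resolution-driven class effect under the stated assumptions — they do not
validate the thresholds against real imagery.

## Problem sizes used by the test-suite experiments

Unit tests run on lattices up to 200×200 where brute-force oracles
(all-pairs distances, naive morphology, connected-component labeling) are
affordable. The pipeline-recovery experiments run the full chain at the
default 1,000 m extent across ten seeds, and one complete run at
2,000 m × 2,000 m; these sizes were chosen so the whole suite exercises
every stage at full fidelity while remaining comfortable to run routinely.

## Known limitations

* GeoTIFF support covers uncompressed strip layouts with the standard geo
  tags (which the package itself writes, and which common GIS tools read);
  compressed or tiled third-party files must be converted first. Vector
  I/O is GeoJSON.
* Polygon intersection testing (vertex containment plus edge crossing) is
  exact for the simple convex-ish parcels and boundaries the pipeline uses,
  but does not handle pathological self-intersecting geometries.
* The mixel mechanism uses exact block means; a real sensor's point-spread
  function smears across cell boundaries, so real lone-tree detectability
  is somewhat worse than the synthetic model suggests.
* Stage boundaries are razor-sharp distance thresholds; no uncertainty is
  propagated into the staging.
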