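---
title: "Per-tree canopy analytics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-tree canopy analytics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopy3d)
```

# Scope

`canopy3d` turns UAV photogrammetric rasters — a digital surface model
(DSM) and multispectral bands — into per-tree traits for orchards:
height, crown diameter, projected area, canopy volume, mean NDVI, plus
seasonal water-status analytics from stem water potential (SWP) series
and the regression toolkit used to validate image-based estimates
against field measurements. This vignette records the model, the
parameter choices and their rationale, and the numerical decisions that
are not obvious from the function documentation.

# The processing model

## Terrain and the canopy height model

A DSM contains terrain plus objects. Per-tree heights and volumes need
heights *above ground*, so a digital terrain model (DTM) is
reconstructed from the DSM itself:

1. **Provisional canopy mask** (`provisionalCanopyMask`): the DSM is
   reduced to a coarse block grid (5 m blocks); the 30th percentile of
   each block estimates local ground, and pixels more than 0.5 m above
   it are flagged as canopy, then dilated by 3 pixels for a safety
   margin. This mask only has to be *conservative* — it may overgrow
   crowns, it must not leak crown pixels into the ground sample.
2. **Ground sampling** (`sampleGroundPoints`): one point per 2.5 m grid
   cell, taken at the 10th percentile of the unmasked DSM values in the
   cell — a low quantile rejects residual low vegetation while staying
   robust to single-pixel noise. In an orchard at 5 × 5 m spacing this
   samples the inter-row and intra-row corridors densely.
3. **TIN interpolation** (`buildDtm`): the points are triangulated with
   a Delaunay (Bowyer–Watson) algorithm and each triangle is
   rasterised with barycentric (linear) interpolation. Outside the
   convex hull, nearest-sample extrapolation fills the margins.

The nDSM (canopy height model) is `computeNdsm(dsm, dtm)`, clamped at
zero because negative canopy heights are physically meaningless;
nodata propagates.

**Numerical note — degenerate triangulations.** Ground points sampled
on a regular grid are maximally degenerate for Delaunay algorithms:
every 2 × 2 cell is cocircular. The triangulator applies a
deterministic symbolic jitter (about 1e-9 of the coordinate scale,
derived from a hash of each point's coordinates) before triangulating,
then interpolates with the original coordinates. Results are exactly
reproducible and the perturbation is orders of magnitude below the
raster discretisation error.

## Crown segmentation

Crowns are separated from soil on the nDSM by local adaptive
thresholding (`localThreshold`):

* Niblack: foreground iff `v > m + k·s` (default `k = -0.2`);
* Sauvola: foreground iff `v > m·(1 + k·(s/r − 1))` (default
  `k = 0.5`, `r` = half the value range);

with `m`, `s` the mean and population standard deviation in a square
window clipped at image borders, and equality always classified as
background. The default window adapts to resolution: roughly 1.5 ×
the expected 3 m crown diameter, in pixels, forced odd — wide enough
that every window sees both crown and ground.

**Design decision — the soil/tree floor.** Over bare inter-row ground
the nDSM is near zero and its variance is pure DTM-interpolation
noise; a local threshold happily carves "crowns" out of that noise.
The method therefore additionally requires `v > heightThreshold`
(default 0.5 m) as a soil/tree delimitation floor. Setting
`heightThreshold = -Inf` recovers the pure Niblack/Sauvola decision
(the test suite uses this to compare against a brute-force oracle).
A plain fixed threshold (`method = "fixed"`) is also provided.

Masks are labelled as **8-connected** components (`labelCrowns`, a
run-merging union–find; diagonal contact joins components), and
components below `minArea` (default 0.5 m²) are dropped. Labels are
assigned in raster-scan order of each component's first pixel, which
makes labelling deterministic.

## Per-tree geometry

* **Height** (`treeHeight`): crown apex elevation minus the mean DTM
  in a ring around the crown (default 2 px wide, excluding all crown
  pixels) — apex minus surrounding terrain, robust to within-crown DTM
  artefacts.
* **Diameter** (`crownDiameter`): equivalent-circle diameter
  `2·sqrt(A/π)` of the projected footprint; for an elliptic crown this
  is the geometric mean of the two axis diameters.
* **Volume**: per-pixel integration `totalVolume = Σ area × height`
  over the crown pixels; the hidden below-canopy prism
  `belowCanopyVolume = area × d` is subtracted
  (`netCanopyVolume`, clamped at zero with a warning). The clearance
  `d` is either an orchard mean (0.7 m default) or per-tree crown-base
  heights supplied as a table; a missing per-tree entry is an error,
  not a silent fallback.
* Closed forms: `ellipsoidVolume` implements
  `V = (4π/3)(D1/2)(D2/2)((Ht − Hb)/2)` and `tcsa` the trunk
  cross-sectional area `C²/(4π)` from circumference.

## Spectral vigour and water status

`ndvi` is strict map algebra `(NIR − RED)/(NIR + RED)` on aligned
reflectance grids in [0, 1]; a zero denominator yields nodata, not
NaN. `perTreeNdvi` averages valid crown pixels. `spadToCab` applies
the chlorophyll calibration `Cab = 0.8271·SPAD − 12.8` (negative
results warn: outside the calibration's domain).

`waterStressIntegral` implements the Myers integral
`WSI = |Σ (Ψ̄_i,i+1 − c)·n_i|` with `c` the maximum SWP of the
analysed window (or a fixed `cRef` for treatment-level comparisons)
and `n_i` the interval length in days; `dailyWsi = −WSI / n_days`.
Irrigation arithmetic: `irrigationRequirement(etEff, kc = 0.55,
kr = 0.46)` and `perTreeIrrigation(volumePerHa, spacingX, spacingY)`
(litres per tree = m³ ha⁻¹ × tree footprint share).

## Validation statistics

`fitOriginForced` (slope `Σxy/Σx²`, *uncentered* R² — the centered
form can be negative for origin-forced fits), `fitOrdinary` (OLS),
`fitBilinear` (breakpoint by profiling `y ~ x + max(x − c, 0)` over a
200-point grid on the range of `x`; the breakpoint is flagged
non-identifiable when the profiled SSE is flat to within 1e-8 of its
scale), and `fitMultiple` (two predictors, collinearity is an error).
All return a `RegressionResult` with coefficients, R², RMSE and `n`.

# The synthetic orchard generator

Field rasters are too large to ship, so testing is built on
`generateScene(sceneConfig(), seed)`: a deterministic scene with exact
per-tree truth. What it emulates — and what it deliberately does not:

* **Terrain**: a planar gradient (defaults 0.01 in x and y) plus
  smooth sinusoidal undulation (0.10 m amplitude at 20–50 m
  wavelengths). Emulates gentle orchard topography; no cliffs,
  ditches or photogrammetric doming.
* **Crowns**: half-ellipsoids, `z = terrain + Hb + c(1 + sqrt(1 − r²))`,
  with per-tree axes `D1, D2 ~ U(2.0, 3.8)` m, heights
  `Ht ~ U(2.1, 3.9)` m, crown base `Hb ~ N(0.7, 0.05)` m on a 3 × 5
  grid at 5 × 5 m spacing, 2 cm GSD. The configuration validity
  rejects axes that could overlap neighbours. An optional hollow
  vase-core depression (`hollowCoreFraction`) lowers the crown centre;
  its volume deficit has a closed form, so truth stays analytic.
* **Spectra**: crown NDVI is driven by a per-tree leaf area index
  (`0.30 + 0.40·LAI/LAI_max` plus N(0, 0.02) noise), soil NDVI 0.10;
  NIR/RED reflectances are back-computed as `0.3(1 ± NDVI)`. This is a
  monotone NDVI–LAI link for rank-level tests, not a radiative
  transfer model.
* **SWP seasons** (`generateSwpSeries`): weekly DOY 182–273 series;
  irrigated oscillates near −1.8 MPa, rainfed declines to about
  −4.5 MPa with a mid-season rain-relief bump. These reproduce the
  *ordering* (rainfed accumulates more stress) rather than any
  specific field season.

All generator parameters were fixed a priori as plausible orchard
values; they are the study conditions, not tuning knobs.

**The analytic volume oracle.** For a solid half-ellipsoid crown the
nadir integral of `z_top − ground` over the footprint is exactly
`(5/3)·π·a·b·c` — 1.25 × the ellipsoid volume `(4/3)·π·a·b·c`. The
whole raster chain (scene → nDSM → segmentation → per-pixel
integration → prism subtraction) can therefore be checked against a
closed form, down to discretisation error.

**Numerical note — lattice oscillation in convergence tests.** The
volume discretisation error has two parts: a smooth O(gsd) term from
the crown rim and a lattice-counting term (how many pixel centres fall
inside the elliptic footprint — a Gauss-circle-problem error) that
*oscillates* with gsd. For random crown sizes the oscillating term can
make error-vs-resolution non-monotone at the 1e-4 level. Convergence
checks therefore use one canonical crown (D1 = 3, D2 = 2, Ht = 3.4,
Hb = 0.7 m, flat noise-free terrain), for which the error sequence at
4/2/1 cm GSD is cleanly monotone (2.0e-3, 8.0e-4, 1.1e-4 relative).
This is a deterministic configuration choice, not seed selection.

# Raster storage

No GeoTIFF writer is assumed. `writeRaster` stores a `RasterGrid` as:

* a 32-bit float TIFF whose values are affinely mapped into
  [0.25, 1], with nodata coded as exactly 0 (the gap below 0.25 makes
  nodata unambiguous under floating-point rounding);
* an ESRI world file (`.tfw`) with the affine georeferencing;
* a JSON sidecar (`.aux.json`) with `value_offset`, `value_scale`,
  `low_code`, `nodata`, `units` and `crs`.

Round-trip precision is about 2e-10 relative. Geographic
(degree-based) CRS strings are rejected: all geometry here assumes
metric, square-pixel grids. Pixel centres follow the usual convention
`x = xmin + (col − 0.5)·px`, `y = ymax − (row − 0.5)·py`, row 1 north.

# Problem sizes and defaults

| Quantity | Default | Rationale |
|---|---|---|
| Scene | 3 × 5 trees, 5 × 5 m, 2 cm GSD (~1000 × 1750 px) | analyses in seconds, errors well below tolerances |
| Ground sample grid | 2.5 m | half the tree spacing: dense corridors, no crown cells |
| Threshold window | auto ≈ 1.5 × 3 m diameter | window must straddle crown and ground |
| `heightThreshold` | 0.5 m | above DTM noise, below any plausible crown |
| `minArea` | 0.5 m² | rejects noise blobs, keeps the smallest real crowns |
| Clearance `d` | 0.7 m | typical trained-orchard crown base |
| Bilinear grid | 200 points over range(x) | breakpoint resolution ≪ practical noise level |

# Limitations

* Crowns that touch merge into one segment; no watershed splitting.
* The TIN DTM is linear per facet; strongly curved terrain between
  ground samples biases heights by O(curvature × spacing²).
* The generator's spectra are schematic; NDVI tests are rank-level.
* Thresholding assumes height contrast; it cannot separate crowns
  from tall cover crops.
* The bilinear fit profiles a single breakpoint; multiple-kink
  responses need a different model.
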