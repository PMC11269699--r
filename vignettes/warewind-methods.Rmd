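---
title: "Methods: wind-rotated NO2 composites, traffic, and exposure disparities near facilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wind-rotated NO2 composites, traffic, and exposure disparities near facilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Warehouses and similar point facilities attract heavy-duty truck traffic
whose nitrogen oxide emissions raise local NO2. Individually the signal of
one facility is far below the noise floor of a daily satellite retrieval;
aggregated over many facilities and days it becomes measurable. `warewind`
implements that aggregation: daily near-facility windows of a gridded NO2
column field are rotated into a common wind-aligned frame, composited, and
summarised by an upwind-edge enhancement statistic; near-facility truck
traffic and census-tract demographics are then linked to the same facilities.

Because the real registry, retrieval, reanalysis, traffic and census
products are proprietary or very large, the package includes a seeded
synthetic-scenario generator that emulates their statistical structure and
records ground truth, so every stage is testable by parameter recovery on a
desk-scale problem.

## The composite and the enhancement statistic

For each facility *i* and day *d*:

1. **Prevailing wind.** Hourly coarse (0.25 degree) zonal/meridional winds
   are bilinearly interpolated to the facility and vector-averaged over the
   satellite-overpass window. The flow direction is the arctangent of the
   mean components (the vector-mean convention for circular data); the
   speed is the norm of the mean vector. If the mean vector vanishes the
   day is *calm*: the direction is undefined and the day is dropped from
   rotation composites.
2. **Rotation.** A buffered window (radius `ceiling(R * sqrt(2))` cells, so
   rotated corners stay covered) around the facility is inverse-mapped
   through a rotation by the flow direction and bilinearly resampled. In
   the resulting *wind frame* the +east axis points downwind, so the
   leftmost column is the upwind orthogonal edge.
3. **Compositing.** Rotated daily windows are averaged per cell with
   contribution counts — first across days within a facility, then with
   equal weight across facilities (two-stage; a pooled mode exists). The
   two-stage order prevents facilities observed on more clear-sky days
   from dominating.
4. **Enhancement.** The statistic is
   `100 * (peak - edge_mean) / edge_mean`, where `edge_mean` is the mean of
   the upwind-edge cell set and `peak` the maximum of the composite. Since
   the maximum can never be below the mean of any cell subset, the
   enhancement is nonnegative by construction. The peak offset (in
   downwind/crosswind cells) gives the displacement; only the downwind
   component is reported as kilometres, at the nominal cell size.

Defaults: window radius `R = 7` cells (a 15 x 15 window, about +-7 km on a
0.01 degree grid at 1 km nominal cell size), overpass hours 16-20 UTC
inclusive (five hourly samples bracketing an early-afternoon overpass over
the continental U.S.; the endpoint convention is configurable because
"16-21 UTC" phrasing is ambiguous), QA threshold 0.75 for footprint
oversampling, and the full 15-cell leftmost column as the upwind edge. The
edge cell set is configurable (`edge_cols`, `edge_rows`): descriptions of
this statistic sometimes quote fourteen edge cells for a +-7 window, which
cannot be reconciled with a 15-cell column, so the full valid column is the
default and any subset can be supplied.

**Numerical choices.** Grid cells are cell-center registered with the
south-west cell first; nearest-cell ties on cell boundaries resolve to the
lower index. Composite argmax ties resolve toward the window center (a
uniform composite therefore reports zero offset), then to the lowest
index. Rotation uses bilinear interpolation with invalid-cell propagation;
a nearest-neighbour mode exists and is exact for quarter-turn lattice
symmetries. Footprint-to-grid oversampling weights by footprint/cell
overlap area from polygon clipping in the lon/lat plane — no spherical
correction, consistent with the small-cell approximation; ~1 km cells are
treated as exactly 1 km x 1 km with no latitude correction (real-data users
can supply the true cell size via `cell_km`).

## Traffic

Road segments carry annual average daily traffic (AADT) totals and a truck
class group (classes 4-13). `VKT = AADT x length` converts counts to
vehicle kilometres travelled; state totals can be scaled exactly to a
reference activity database. Rasterization apportions each segment's VKT
by the exact fraction of its length in each cell (splitting at grid-line
crossings), which conserves total VKT to rounding error under any
resolution. Near-facility traffic is the window sum. The association
between truck VKT and a facility characteristic is estimated by simple
least squares *within deciles of total VKT* — binning on total traffic
controls for baseline volume — with a two-sided Wald t test per bin, the
mean slope across bins as the headline number, and retained residuals for
normality diagnostics. Regressions are univariate by design: one slope per
characteristic per bin is the reported quantity, and parking spaces are
fitted scaled by 10 so the slope reads "per 10 parking spaces". Facilities
missing a characteristic are dropped from that characteristic's regression
only; instead of imputation, the package reports Spearman correlations
between missingness indicators and NO2, density, demographics and traffic
(`missingness_correlation`), the standard robustness check that incomplete
records are not concentrated where it would bias results.

## Demographics and exposure

Tracts carry six non-mutually-exclusive subgroup populations (white;
non-Hispanic; Hispanic; Black or African American; Asian, Native Hawaiian,
or Pacific Islander; some other race or two or more races), so shares need
not sum to one; Hispanic and non-Hispanic partition the total. Population
density classes use fixed thresholds (< 267 people/km2 Low, 267-1501
Medium, > 1501 High; boundaries assigned to Medium) or supplied-data
tertiles. Siting disparities compare the median tract share of each
subgroup among facility-containing tracts ("Any", and deciles of the
per-tract facility count — "clustering") against the all-tract median:
relative difference of medians plus a two-sample Kolmogorov-Smirnov test.
Medians of tract shares, not population-weighted means, define the
composition comparison.

Exposure uses population weighting over facilities:
`NO2_pw = sum_i(NO2_i * pop_i) / sum_i(pop_i)`, with `NO2_i` the spatial
mean of facility *i*'s near-facility window of the period-mean field and
`pop_i` the subgroup population of its tract. Subgroup values are reported
as percent differences from the total-population value. No significance is
attached to these: they are comparisons between pairs of single values,
not distributions. State-level tables and a leave-states-out recomputation
expose geographic heterogeneity of the disparities.

## The statistical kernel

Spearman rank correlation (average ranks for ties; two-sided t
approximation), the OLS slope with its Wald t test, the Mann-Kendall trend
test (tie-corrected variance, continuity-corrected normal approximation,
no seasonal adjustment — the intended input is an annual series), and the
two-sample KS statistic are implemented directly and are verified against
brute-force oracles and the corresponding base-R tests in the suite. KS
p-values are asymptotic by default (the Kolmogorov series), with an exact
small-sample option. Decile displays report per-bin medians with 95
percent bootstrap percentile intervals (1000 resamples by default; the
interval method is a package choice since none is canonical), while
correlation and significance are always computed on the unbinned data.
Decile assignment is rank-based with ties to the lower bin everywhere.

## What the synthetic generator emulates — and what it does not

Each sub-generator draws from its own seed stream derived from the master
seed, so scenarios are bit-reproducible and adding facilities does not
perturb the winds.

* **Tracts**: a rectangular tract lattice over a smooth two-center
  population-density surface (peaks near 4000 people/km2 over a 30
  people/km2 floor, so all three density classes occur); subgroup shares
  follow smooth logistic gradients along random directions with tract-level
  jitter.
* **Facilities**: a parent/offspring clustered point process. Parent tracts
  are drawn proportional to population times `(subgroup share)^siting_bias`
  — bias 0 is population-weighted, demographically unbiased siting.
  Characteristics (building area, docks, parking) share a latent Gaussian
  with 0.6 cross-correlation; docks and parking are masked missing
  completely at random at the documented real-world rates (40.7% / 31.1%).
* **Winds**: AR(1) day-to-day means, AR(1) hourly deviations, small random
  spatial gradients; a constant-wind override supports degenerate tests.
* **NO2**: background (base 2 column units plus a density term) plus one
  isotropic Gaussian plume per facility (sigma 1.5 km), displaced 4 km
  downwind of the facility along that day's overpass wind, with amplitude
  linear in loading docks and co-tract facility count; mean-one lognormal
  noise (cv 0.3) and 30% random missing cells per day emulate retrieval
  noise and swath gaps. The isotropic Gaussian is the simplest shape with
  a well-defined displaced peak; the linear clustering term is the simplest
  monotone choice.
* **Roads**: a lattice along tract center lines with density-scaled AADT,
  plus a 1 km access segment per facility whose truck AADT follows the
  structural slopes (1456 km per dock, 485 per co-tract facility, -13 per
  parking space over a 5000 km/day base with 2000 km/day noise — the base
  is sized so the dock signal and baseline are comparable).
* **Emissions**: eight nonnegative sector rasters whose sum is the total;
  the on-road sector is proportional to the VKT raster; agricultural
  ammonia is deliberately absent (it carries no NOx).

Not emulated: orbital geometry, retrieval stripes or physics, albedo and
cloud screening, NO-to-NO2 chemistry (the displaced peak is planted, not
derived), routing or traffic assignment, and census margins of error.
Passing recovery tests therefore demonstrates the correctness of the
estimator chain under a known data-generating process — not that real
retrievals satisfy that process.

**Ground truth.** The generator records two truths. Per facility, the
analytic enhancement `100 * amplitude / background` of an isolated plume.
At composite level, the enhancement statistic evaluated on the *noise-free,
unmasked* fields: clustered neighbours' plumes genuinely overlap in the
composite, so the noise-free-field value (not the isolated-plume sum) is
the quantity the estimator should reproduce, and the remaining recovery gap
in tests isolates exactly the effect of retrieval noise and swath masking.
The background/density coefficient default (5e-4 column units per
person/km2) is a free parameter chosen to give city backgrounds about 1.5x
the rural floor; it is not an estimate of any real relationship.

For the planted traffic slopes the recorded recovery target is the
*univariate* slope implied by the generator — the structural per-dock slope
plus the covariance contribution of correlated parking and clustering —
because the estimator is deliberately univariate. The clustering slope has
no clean univariate target (neighbouring facilities' access roads fall
inside the shared window), so recovery is asserted for docks.

## Problem sizes and reproducibility

The reference scenario used by the tests and the acceptance script is 200
facilities over 60 days on a 150 x 150 cell grid with 225 tracts and 3
states; it runs in well under a minute. The test suite regenerates it once
and additionally uses ~30-facility scenarios for smoke and determinism
checks. `run_pipeline()` writes every table as CSV plus a JSON manifest
with the config hash, seed, versions and per-file checksums; identical
config and seed reproduce byte-identical tables. Serialization is CSV/JSON
throughout (grid metadata travels in a JSON header), keeping scenarios
plain-text and diffable.

## Known limitations

* The enhancement statistic cannot attribute composite NO2 to individual
  facilities within a cluster; stratifying by clustering level is the
  supported alternative.
* A composite maximum over a noisy field is upward-biased when counts per
  cell are small; with few facilities or days the enhancement is
  overestimated. At the reference scale (thousands of contributions per
  cell) the bias is below 2 percent.
* The displacement is reported in whole cells; sub-cell displacements are
  not resolved.
* Bilinear resampling slightly flattens a plume peak (up to ~11 percent of
  the amplitude for a 1.5-cell sigma), which is why isolated-facility
  recovery is asserted at that tolerance while composite-level recovery
  uses the noise-free-field truth.
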