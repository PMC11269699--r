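# warewind

Satellite columns of NO2 respond to the truck traffic that point
facilities — warehouses above all — attract. One facility's signal is
buried in the noise of a single daily retrieval; averaged over many
facilities and days in a common wind-aligned frame, it is measurable.
`warewind` is an R package for exactly that analysis: it quantifies
near-facility NO2 enhancements from daily gridded trace-gas fields, links
them to facility characteristics and to gridded truck traffic, and
assesses who lives near the facilities and what they are exposed to. It is
aimed at air-quality and environmental-justice researchers working with
gridded satellite retrievals, road-network traffic counts, and
census-tract demographics.

## The method

For facility *i* on day *d*, the prevailing wind is the vector mean of the
hourly 100-m wind interpolated to the facility over the satellite-overpass
window (16–20 UTC by default): direction from the arctangent of the mean
zonal/meridional components, speed from the norm. The daily near-facility
window (±7 cells of a 0.01° ≈ 1 km grid) is rotated so that +x points
downwind, composited across days and then facilities, and summarised by
the upwind-edge enhancement

```
enhancement (%) = 100 · (max(composite) − mean(upwind edge)) / mean(upwind edge)
```

with the downwind component of the peak offset reported as a displacement
in km. Truck traffic enters as VKT = AADT × segment length, rasterized by
exact length-in-cell apportionment and summed over the same ±7-cell
windows; associations with loading docks, parking spaces (per 10), and
clustering (facilities per tract) are simple regressions within deciles of
total VKT, with Wald *t* tests. Exposure is population-weighted:
NO2_pw = Σᵢ NO2ᵢ·popᵢ / Σᵢ popᵢ per demographic subgroup, compared with the
total-population value; siting disparities compare median tract shares in
facility-containing tracts against all tracts with two-sample
Kolmogorov–Smirnov tests.

A seeded synthetic-scenario generator (facilities, tracts, roads, winds,
daily NO2 fields, sectoral emissions) with recorded ground truth makes the
whole chain verifiable by parameter recovery — no proprietary inputs are
needed anywhere in the package, its tests, or its acceptance script.

## Worked example

```r
library(warewind)

cfg    <- scenario_config(seed = 1)        # 200 facilities, 60 days
scen   <- generate_scenario(cfg)
bundle <- run_pipeline(inputs = scen)
cat(report(bundle), sep = "\n")
```

```
# Near-facility NO2 analysis summary

- Facilities: 200; days: 60
- Composite NO2 enhancement:  23.1% (upwind edge 2.975, peak 3.662)
- Downwind peak displacement:     4 km

## Truck-VKT slopes (mean across total-VKT decile bins)
- per clustering: 1.414e+04 km/day
- per docks:  1078 km/day
- per parking: 735.3 km/day

## Siting disparities (tracts with facilities vs all tracts, median share)
- white: -0.1424%
- non_hispanic: -11.21%
- hispanic: 102.1%
...
```

Reading this: the wind-aligned composite of all 200 facilities peaks 23.1%
above its upwind edge, 4 cells (≈ 4 km) downwind of the facility — against
a scenario truth of 22.7% and 4 km (the generator planted a ≈20% plume
signal displaced 4 km, plus cluster overlap). The mean within-bin slope of
truck VKT on loading docks, 1078 km/day per dock, recovers the planted
univariate slope of 1342 within its across-bin confidence interval. The
scenario sites facilities preferentially in high-Hispanic-share tracts
(`siting_bias = 1`), and the disparity table finds exactly that: the
median Hispanic share in facility tracts is 102% above the all-tract
median. `run_pipeline(..., outdir = "out")` writes every table as CSV
plus a JSON manifest; identical config and seed reproduce byte-identical
tables.

## Package layout

- `R/grid.R` — grid/raster primitives, QA-filtered footprint oversampling,
  bilinear regridding, window extraction
- `R/wind.R` — prevailing winds, wind-frame rotation, compositing, the
  enhancement statistic, stratified variants
- `R/stats.R` — Spearman, OLS/Wald, Mann–Kendall, two-sample KS, decile
  summaries with bootstrap CIs, missingness correlations
- `R/traffic.R` — VKT conversion, state scaling, rasterization,
  near-facility sums, decile-binned regressions
- `R/equity.R` — density classes, siting disparities, population-weighted
  exposure, state-level and leave-out variants
- `R/synthetic.R` — the scenario generator and ground truth
- `R/pipeline.R` — orchestration, reporting, manifests

The methods vignette (`vignettes/warewind-methods.Rmd`) documents the
model, conventions, tunable parameters, and what the synthetic scenarios
do and do not emulate.
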