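---
title: "Methods: agro-climatic feasibility of the boreal zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agro-climatic feasibility of the boreal zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borealgdd)
```

## The question and the model

High-latitude warming may push the climatic envelope of small-cereal
agriculture (barley, oat) northward into the boreal zone. `borealgdd`
implements the standard temperature-sum approach to that question: growing
degree days above a 5 °C base (GDD₅) are the physiological link between
temperature and crop development, and a cell is climatically *feasible* for
small cereals when its annual GDD₅ reaches 1200 °C·day. The pipeline takes
gridded monthly-mean temperature and precipitation per climate model
(0.5° × 0.5° by convention), and produces feasibility masks, equal-weight
ensemble statistics, zonal area tables, per-longitude leading-edge shift
distances, and growing-season water-balance diagnostics.

### Pentad climatologies

To attenuate interannual variability, all downstream computation operates on
*pentads*: each calendar month averaged over five consecutive years. A
pentad is labelled by its end year ("2049" = 2045–2049). Any missing monthly
value inside the window makes that (month, cell) missing downstream — we
never form silent partial averages.

### GDD₅ from monthly means

The inputs carry no daily resolution, so daily sums are approximated by
days-per-month multipliers: months whose pentad mean exceeds the base
temperature (strictly, `T > 5`) contribute `(T − 5) · N_m` degree days,
where `N_m` is the month length on a fixed 365-day no-leap calendar; colder
months contribute nothing, and no upper temperature cap is applied. The
no-leap calendar is a deliberate convention: the source method says only
"days-per-month multipliers", and a fixed calendar keeps results exactly
reproducible while changing annual GDD by < 0.1 %.

Two boundary conventions are fixed and tested rather than left implicit:
month inclusion is strict (`> 5 °C`; a month at exactly 5 °C contributes
zero either way), while the feasibility threshold is inclusive
(`GDD₅ ≥ 1200`). The "frost-free period" of the textbook GDD definition is
operationalized entirely by the month-selection rule; no separate frost
model is used.

How good is the monthly approximation? `generate_daily_temperature()`
provides the independent oracle: a daily sinusoid recentred so each month's
daily mean equals the monthly value. When daily temperatures are constant
within months the two computations agree exactly (this is asserted to
1e-12). For a smooth seasonal sinusoid with amplitude `A`, clipping at the
base temperature only misassigns degree days in months whose daily values
cross 5 °C; within such a month the daily deviation from the monthly mean is
bounded by the maximum seasonal slope times half the month,
`π·A·31/365` (≈ 4 °C for `A` = 15), so each straddling month contributes at
most `π·A·31²/365` ≈ 124 °C·day of error and at most four months can
straddle the base in one seasonal cycle. The acceptance suite asserts
agreement within this a-priori bound (≈ 500 °C·day for `A` = 15); observed
discrepancies are far smaller.

### Thornthwaite PET and the water balance

Potential evapotranspiration uses the classic (uncorrected) Thornthwaite
formulation: per cell, the annual heat index
`I = Σ_{T_m > 0} (T_m/5)^1.514`, the cubic exponent
`a = 6.75e-7·I³ − 7.71e-5·I² + 1.792e-2·I + 0.49239`, and monthly
`PET = 16 · (L/12) · (N/30) · (10·T/I)^a` mm for months with `T > 0`,
else 0. `L` is the monthly mean of daily day lengths evaluated at the cell's
latitude snapped to the nearest 5° multiple — the snapping deliberately
reproduces the banding ("stripes") characteristic of discrete-latitude PET
maps; `snap = FALSE` gives exact-latitude PET. Day length comes from the
standard solar-declination/hour-angle closed form with
`δ = 23.44°·sin(2π(284 + n)/365)`, clamped so polar day/night yield exactly
24/0 h. The hot-month (> 26.5 °C) alternative expression of some
Thornthwaite variants is *not* applied — a boreal-focused simplification,
noted as a limitation.

The growing-season climatic water balance is `C = P − PET` summed over
May–October (configurable), and the aridity index is the seasonal ratio
`p/PET`, undefined (missing) where seasonal PET is zero. Aridity
classification uses a strict `p/PET < 0.65` threshold. Monthly balance
fields are retained so within-season structure (dry springs, wet falls) can
be examined.

Numerical caveat: the exact day-length approximation and Thornthwaite
variant behind the source maps are not documented, so agreement with those
maps cannot be asserted; all PET tests here are against this package's own
documented closed forms.

### Ensemble statistics

Models are combined by equal weighting (1/N, "model democracy"); the mean,
cellwise min/max, and coefficient of variation (sample n−1 standard
deviation over mean, missing where the mean is zero — seven models is a
small sample) are provided. The default missing policy is strict
intersection: a cell missing in any member is missing in every statistic, so
the effective model count never varies by cell (`na_policy = "available"`
relaxes this explicitly).

`compare_scenarios()` addresses whether two scenario families (e.g.
emission-based vs transient-GHG) differ over a set of period summaries. The
"Fisher test" of the source sentence is interpreted as the two-sided
variance-ratio F test, paired with the pooled-variance two-sample Student t
test; the reference's supplementary material is unavailable, so this
interpretation is a documented design choice (Fisher's exact test on a
categorization would be the alternative reading).

### Areas, zonal accounting and the leading edge

Cell areas are exact spherical-cap differences,
`A = R²·Δλ·(sin φ_top − sin φ_bottom)` with `R = 6371` km (mean Earth
radius; the source states no geodesy, so every km figure carries this
convention). Summed globally these telescope to `4πR²` to floating-point
accuracy, and any latitude band sums to its closed-form area — the
conservation property the acceptance suite checks.

Zonal summaries divide feasible by total region area (reported in
10⁶ km²); gains are `final − baseline` with percentage increase relative to
baseline. When reproducing printed tables, rounding is half-up at the
printed precision (R's own `round()` is banker's rounding and differs at
.5). Latitude-band summaries use half-open 5° bands labelled like
"65–69N".

The *leading edge* is defined per longitude column as the northernmost
feasible cell belonging to a run of at least `min_contiguous` consecutive
feasible cells along the meridian (default 1, the raw maximum — the source
never defines its edge, so both the definition and the contiguity parameter
are explicit and configurable). The shift is the meridional arc
`Δφ(rad)·R`, a pure northward component, not a nearest-boundary distance;
columns where the edge newly appears or disappears are flagged
(`new_colonization` / `lost`) rather than given a number.

## The synthetic world

No real GCM output ships with the package. `scenario_spec()` states a
stylized world once and the generators derive everything from it:

```
T(cell, y, m) = T0 + g·|lat| + A·cos(2π(m − 7)/12)·hemisphere
              + w·f_i·(y − y0)/10 + offset_i + N(0, σ)
```

* `T0 = 27` °C at the equator and `g = −0.6` °C/°lat give a realistic
  annual-mean gradient (≈ −15 °C at 70°N);
* `A = 15` °C is a mid-continental seasonal amplitude, peaking in July in
  the north (the boreal May–October season) and January in the south;
* `w = 0.4` °C/decade is an end-of-century warming rate of the right order
  for high-emission scenarios, with per-model trend multipliers 0.7–1.3 and
  mean-zero offsets ±0.9 °C emulating a seven-member ensemble's spread;
* `σ = 0.5` °C monthly cell noise, independent across cells, months and
  models — the simplest null structure.

Precipitation is `P0·(a0 + a1·cos 2φ)` (wet tropics, dry poles; default
`P0 = 70` mm/month, `a0 = 0.7`, `a1 = 0.5`) with the same July-phase
seasonal modulation and multiplicative noise of coefficient of variation
0.1. The spec's single noise parameter is in °C, so the precipitation noise
scale is a separate explicit parameter (`precip_noise_cv`) rather than a
reuse of it.

One master seed drives everything through per-(model, variable, year)
substreams, so regenerating any year of any model in isolation is
bit-reproducible. Note that the warming trend references the *series start
year*: cut pentads from one continuous series rather than generating each
pentad window separately, or the trend restarts at zero.

Region masks are rasterized rectangles: a pseudo-boreal latitude band over
two "land" longitude sectors, disjoint longitude-sector countries that
exactly partition it, and two continents split at the −30°E meridian. What
the synthetic world deliberately omits: real coastlines and topography,
spatially correlated noise, teleconnections and solar cycles, model-specific
physics. A green test therefore establishes that the *pipeline arithmetic*
is right (areas, thresholds, shifts, balances), not that the generator
emulates any particular GCM; the headline real-data numbers of the
motivating analysis are out of reach at desk scale and are not asserted.

The one quantitative bridge between generator and pipeline is parameter
recovery: with noise off and a linear gradient `g < 0`, adding a uniform
ΔT warming shifts the entire temperature field so that
`GDD(φ | +ΔT) = GDD(φ − ΔT/|g|)`, hence the measured leading-edge shift
must equal `ΔT/|g|` degrees to within one grid cell at *every* longitude.
The acceptance suite runs this with `g = −0.8`, ΔT = 2 °C: 2.5° ≈ 278 km,
±0.5° (≈ 56 km) quantization.

## Numerical and degenerate-input choices

* Grids are cell-center registered, half-open in longitude, closed at the
  poles; longitudes normalized to [−180, 180). Center vs corner
  registration of the original data is unknown; center is this package's
  choice.
* Regridding replaces the original Natural-Neighbour interpolation with
  bilinear (fields) / nearest (masks): deterministic and dependency-free,
  and the analysis runs natively at source resolution so regridding is a
  convenience. Bilinear never extrapolates beyond the outermost cell
  centers (outside → missing) and reproduces affine functions exactly;
  nearest covers the full source cell extent (centers ± res/2).
* I/O uses a plain-text long CSV (`year,month,lat,lon,value` with a
  `#`-comment metadata header carrying the units attribute). The
  environment provides no NetCDF bindings, and the CSV format is the
  documented alternative; values, axes and missing flags round-trip
  losslessly. Temperatures that are all > 150 are rejected as Kelvin rather
  than silently converted.
* `p/PET` is missing where seasonal PET is 0; percentage gain is flagged
  undefined where the baseline feasible area is 0; the F/t comparison flags
  the zero-variance-in-both case degenerate instead of returning NaNs.

## Known limitations

Thornthwaite PET is temperature-driven only (no radiation, humidity or wind;
no Penman–Monteith or Hargreaves alternative) and the hot-month variant is
omitted. The feasibility criterion is purely thermal — soils, photoperiod
sensitivity of specific cultivars, and socio-economics are outside the
model, though `photoperiod_profile()` provides the day-length context.
Edge detection is per-column and meridional; diagonal or coastal edge
geometry is not followed. The synthetic generator's limitations are listed
above.
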