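---
title: "Drought, power generation shifts, and the PM2.5 health burden: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drought, power generation shifts, and the PM2.5 health burden: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtpm)
```

## The scientific problem

In regions that rely heavily on hydropower, droughts shift electricity
generation toward combustion power plants (coal, gas, oil, biomass), raising
fine particulate matter (PM2.5) concentrations near those plants and with
them the mortality risk of the surrounding population.  `droughtpm`
implements the full analysis chain for this mechanism:

1. **Hydrological drought exposure** — watershed runoff anomalies and the
   fraction of hydropower capacity affected by drought (FHD);
2. **Plant-level air-quality panel** — radial PM2.5 and meteorology means
   around combustion plants, wildfire exclusion filters, degree-days, and
   Thiessen-partitioned population exposure;
3. **Causal panel estimation** — multi-way fixed-effects OLS of PM2.5 on
   the FHD with market-clustered inference, dose-response bins,
   heterogeneity interactions, and placebo designs;
4. **Mortality counterfactual** — a constant concentration-response
   function (CRF) applied to drought-induced excess PM2.5 with Monte-Carlo
   propagation of the coefficient uncertainty;
5. **Valuation** — income-extrapolated values of statistical life (VSL);
6. **Projections** — scenario ensembles of future drought exposure,
   demographic and economic scalings, and plant-retirement schedules.

Because the real inputs are continental-scale geospatial archives, the
package ships a **synthetic-world generator** whose data-generating process
(DGP) is known exactly.  Every stage of the pipeline can therefore be
verified against ground truth at desk scale; the package's tests are those
verifications.

## Drought exposure

Runoff (mm/h) lives on a coarse monthly grid.  For each hydropower plant
the watershed is delineated by tracing all upstream basins whose
downstream-pointer path reaches the plant's outlet basin
(`delineate_watershed()`); the watershed runoff series is the unweighted
mean over member cells.  Anomalies subtract the **calendar-month
climatology** over the reference period (2000–2019 by default) — a grand
mean would conflate drought with seasonality.  A trailing `k`-month moving
average (default `k = 3`, including the current month) defines the drought
indicator: a plant is *in drought* when the rolled anomaly is strictly
negative, and *in severe drought* when it is more than one reference
standard deviation below normal.  Two reading choices the source material
leaves open are fixed here and unit-tested: the window is trailing (months
`t-k+1 .. t`), and watershed cell means are unweighted (grid cells are
near-equal-area at this scale); both are switchable assumptions in the code.

The market-level exposure, the **FHD**, is the capacity-weighted share of a
market's hydropower plants in drought (one market = one country; a merged
market mapping is supported for robustness exercises).  Markets without
hydropower capacity carry *missing* exposure, not zero, and fall out of the
analysis sample.  An indicator of exactly zero anomaly is treated as "not
drought"; a numerical guard of 1e-10 below zero keeps floating-point dust
from registering as drought in degenerate (exactly-average) inputs.

## The panel regression

The benchmark model regresses plant-month PM2.5 on the market FHD with
plant, month-by-year, and market-by-calendar-month fixed effects, linear
meteorological controls (temperature, precipitation, relative humidity,
surface pressure, wind at 10 m and 100 m, a local drought indicator) and
market degree-days (HDD/CDD; 18 °C reference, 15 °C / 21 °C activation
thresholds with `days * |T - 18|` accrual).  Errors are clustered at the
market level.

Implementation choices:

* Samples up to 5,000 rows are solved **exactly on the dummy design** (QR
  with rank detection); larger samples use **alternating-projections
  demeaning** (tolerance 1e-10, max 10,000 sweeps).  The two routes agree to
  1e-8 by the Frisch–Waugh–Lovell theorem, and the test suite asserts this.
* The clustered covariance is the **CR1 sandwich** scaled by
  `G/(G-1) * (N-1)/(N-K)`, matched in tests against a brute-force
  per-cluster loop at 1e-10.  On the demeaning route, `K` counts the
  absorbed effects as `L_plant + L_my + L_cm - 2 - (G - 1)`: the three
  dummy blocks share two global constants, and the market indicators lie in
  the span of both the plant and market-month blocks.  This count is exact
  for connected designs of this FE triple.
* p-values are two-sided t with `G - 1` degrees of freedom — standard
  practice with few clusters (19 markets in the default world).
* Singleton fixed-effect groups are dropped iteratively (and counted)
  before estimation: a level with one observation is fit perfectly by its
  own effect and contaminates inference.
* A regressor with no within variation is reported by name as absorbed
  rather than silently dropped.
* The *baseline prediction* ("PM2.5 in the absence of drought") is the
  sample-mean prediction with the exposure set to zero,
  `mean(y) - beta * mean(FHD)`; `implied_total()` adds `beta * FHD` back.
  This is an interpretation of a quantity the source material does not
  define by formula, and it reproduces the published worked examples
  exactly.

The dose-response variant discretizes the FHD into `[0, .25)`, `[.25, .5)`,
`[.5, .75)`, `[.75, 1]` with the lowest bin as reference; heterogeneity
variants interact the FHD with a plant-size indicator (30 MW cut) or fuel
type and report per-subgroup marginal effects with delta-method errors from
the cluster covariance.  Two placebo designs re-run the estimator where no
generation-shift effect should exist: around non-combustion plants with no
combustion plant within 50 km, and in plant-months before commissioning.

## Health burden and valuation

Excess PM2.5 in a market-month is `beta * FHD`.  Monthly premature deaths
among adults 65+ follow the constant-rate CRF

```
deaths = rate * days * excess * pop65 / 1e6
```

with `rate = 0.69` daily deaths per million 65+ per µg/m³ and `days = 30`
(calendar-true month lengths are a config option, off by default).
Alternative CRFs plug in by swapping the `crf_spec()` only.  The exposed
population is Thiessen-partitioned within 50 km (no double counting — the
per-plant totals conserve the union population exactly), linearly
interpolated between 5-year census steps, and scaled by the country-year
65+ fraction (uniform age structure within country).

Uncertainty propagation draws the coefficient 1,000 times from
`N(estimate, SE)` — the published benchmark corresponds to `N(1.55, 0.31)` —
and recomputes deaths per draw.  Draws with negative coefficients are kept:
the Monte Carlo represents estimation uncertainty, and truncation would
bias the distribution (the probability is ~3e-7 at the default moments).
Deaths are linear in the drawn coefficient, so aggregation before or after
the draw expansion is exactly equivalent; the implementation exploits this
and the tests assert it.  A 21-year panel with 1,000 draws yields exactly
21,000 region-year simulation units.

Valuation multiplies deaths by country-year VSLs extrapolated from a US
base value with unit income elasticity:
`VSL_cy = base * (GNI_cy / GNI_US,y)^elasticity`.  The base VSL default
(7.0e6 USD-2019) is a **placeholder of plausible magnitude, not an
authoritative estimate** — the meta-analytic base value is a required
config input in any real application.  All monetary outputs are constant
2019 USD; no deflation happens inside the pipeline.

## Projections

A synthetic climate ensemble (22 models × 3 SSP-RCP scenarios by default →
66 paths) applies per-model drying trends, scaled by scenario severity,
as a smooth ramp on the historical climatology with multiplicative weather
noise.  Projected FHD uses the *historical* climatology — exactly the same
drought machinery as the historical analysis.  The first `k-1` projection
months have no rolled anomaly (trailing window with no prior history) and
contribute zero deaths in the first projection year; this is documented
here rather than backfilled from historical months.

Deaths and losses per path combine the projected FHD with the constant CRF
and coefficient (no adaptation, no technological change), scenario
demographic multipliers on the exposed 65+ population, and the paired
energy-policy retirement schedule (SSP1-2.6↔APS, SSP2-4.5↔STEPS,
SSP3-7.0↔RES by default; the pairing is overridable and the quantity paths
are config inputs).  Plants retire **largest exposed population first**
(ties by plant id) and contribute zero deaths from their retirement year;
no new combustion plants are ever added.  RES retires nothing.

## The synthetic world

The generator emulates the *structure* of the real inputs — monthly mm/h
runoff grids, 0.25° meteorology/fire grids, 0.01° PM2.5 and population
rasters, plant registries with capacity/fuel/commissioning year, GNI and
age-structure country tables — with no attempt at real geography.  Key
design features:

* **Stream-split randomness.** Each component (layout, runoff, meteorology,
  effects, noise, fire, population, country tables) draws from its own seed
  derived from the global seed, so toggling one component never shifts
  another — the tests assert this ablation stability.
* **Geometry.** Each market occupies one tile: a basin window for
  hydropower, then one slot per combustion and non-combustion plant spaced
  1° apart, so 50 km dispersion radii never overlap across plants or
  markets.  Within each slot a 0.3° fine raster at 0.01° supplies PM2.5 and
  population.  This makes the measured radial PM2.5 mean around each plant
  equal that plant's DGP value exactly (plus cell noise that averages out),
  so the generator honours its contract: with zero noise the measured panel
  reproduces the linear DGP to machine precision, and the estimator is
  unbiased for the true effect.  Overlapping-radius behaviour (Thiessen
  partitioning, nearest-assignment ties) is exercised by constructed
  fixtures in the unit tests instead.
* **Runoff.** A positive seasonal cycle per basin, identical across years,
  with multiplicative drought episodes per hydropower watershed (random
  start, geometric-like duration around 3 months, 20–60% depth).  With an
  episode rate of zero the world has exactly zero anomalies and FHD — a
  degenerate case the tests use.  Plant-site runoff cells carry independent
  dry spells so the local-drought control varies without being tied to the
  FHD.
* **PM2.5 DGP.** `plant effect + month-year effect + market-calendar-month
  effect + controls·gamma + beta·FHD·operational + noise`, where the
  controls are the *measured* radial means (the generator and panel
  assembly share one code path) and the drought response exists only from
  the commissioning year onward — which is what makes the pre-operational
  placebo meaningful.  Non-combustion plants carry no beta term, grounding
  the other placebo.  Market mean temperatures span 12–26 °C so both HDD
  and CDD vary somewhere in every world.
* **Fires** occur as random emission events on the coarse grid and drive
  the exclusion filter, but do not feed the PM2.5 surface; the filter is
  exercised structurally, and a contaminated-PM extension would sit in the
  painting step.

What passing tests on this world do *not* show: robustness to real
atmospheric transport, correlated met/runoff fields, plant-level capacity
changes over time, or misspecified (non-linear) dose response.  The
synthetic world is a verification harness, not a climate model.

## Study sizes used in the tests

The default world has 19 markets (the analysis-market count of the study
the pipeline reproduces), 3 hydro + 4 combustion + 2 non-combustion plants
per market and 252 months (2000–2020), giving a 19,152-row combustion
panel.  The 200-seed estimator-recovery study runs at a reduced replication
scale chosen to keep the whole suite fast on one CPU — the same DGP and the
same 19-market cluster structure, with 2 combustion plants per market,
11 years, and a coarser (0.1°) PM raster; recovery and coverage properties
do not depend on raster resolution, which only sets the measurement-noise
averaging.  Module tests use 2–4 market worlds.

## Reproducibility

`run_pipeline()` executes the stages in dependency order from a single
config (YAML-loadable via `read_run_config()`), derives per-stage seeds
from one global seed, logs rows in/out per stage, and writes a JSON
manifest with MD5 hashes of every artifact; identical config and seed
reproduce identical hashes.  The package functions are the command surface:
each stage is a plain R call, and the manifest makes sample-construction
accounting (how many plant-months each filter removes) auditable on any
input.

## Known limitations

* Only a constant-rate CRF is implemented; relative-risk CRFs enter as
  config values, not functional forms.
* Reservoir storage does not modulate the drought indicator (run-of-river
  vulnerability is the motivating setting).
* The local-drought control mirrors the hydro definition at the plant's own
  grid cell; the source material does not specify its construction.
* Cluster-robust inference with 19 clusters under-covers mildly; the
  acceptance band for empirical coverage (88–99%) reflects this.
* Wild cluster bootstrap, spatially correlated (Conley) errors,
  post-double-selection control selection, and spline asymmetry analyses
  are out of scope.
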