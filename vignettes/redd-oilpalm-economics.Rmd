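---
title: "Methods: fine-scale REDD+ versus oil-palm economics"
author: "floodcarbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale REDD+ versus oil-palm economics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodcarbon)
```

## The problem

Floodplain forests in Southeast Asia are biologically rich, typically
logged-over, and titled for conversion to oil palm — a crop with some of
the highest agricultural opportunity costs in the tropics. Whether a
carbon-payment mechanism (REDD+) can financially out-compete conversion
depends on three things that vary strongly *within* a floodplain: the
standing forest carbon, the carbon the replacement palms would store (the
reference level), and how well palms actually grow on land that floods.
`floodcarbon` models all three at the level of landscape strata — units of
(carbon class × oil-palm suitability × tenure × extent) — and allocates
each stratum to whichever land use has the higher annualised net present
value. This vignette documents the models, their parameters and the
design decisions.

## Forest carbon

Per-stem above-ground biomass uses a moist-tropical allometry in DBH and
wood density only. Heights are deliberately absent: floodplain inventories
rarely record them, and because plot carbon is subsequently binned into
broad classes, the extra error from a height-free form has little effect
on class assignment. Wood densities fall back to a conservative
0.5 g/cm³ when a species is not in the lookup table.

The AGB→carbon fraction is not fixed by convention everywhere in the
literature (0.47 and 0.5 both circulate); we default to **0.5** and expose
it (`carbon_fraction`). Class-level results depend only weakly on it
because the classes are 50–100 MgC/ha wide.

Class boundaries are **half-open and lower-inclusive** — [0,50), [50,100),
[100,200), [200,300), [300,400), [400,∞) — a convention that must be fixed
somewhere because labels like "50–100" are ambiguous at the edges; a plot
at exactly 50 MgC/ha is class 2. Mid-points (25, 75, 150, 250, 350, and a
conservative 450 for the open top class) drive all stock accounting, so
stocks are exact integers whenever extents are: accounting over the
study's unprotected extents gives 4,705,750 MgC on 30,173 ha
(mean 156 MgC/ha), and 50,228,600 MgC over all forest. The published
tenure table totals 4,705,900 MgC — 150 MgC above the class-table total
(and its own rows sum to 4,705,902); the package reproduces the class-table
arithmetic exactly and leaves that internal discrepancy visible rather
than resolving it.

## The oil-palm reference level

REDD+ credits only *net* carbon: the class mid-point minus what the
replacement plantation would hold, time-averaged over the 25-year crop
life. Per-palm carbon is observed at scattered ages (the default
emulates surveys at ages 2–5, 7–8, 13, 15–16, 18–19). Completion rules:
a single missing year takes the mean of its flanking years; consecutive
missing years get equal annual increments (linear interpolation); ages
before the first observation are back-filled with the first observed value
(conservative, and near-negligible carbon is at stake in years 1–2);
and the oldest observation (age 19) is held for years 20–25.

Downstream economics default to the reference constants **46 / 20 / 7
MgC/ha** for full-stand / 50% / ≤25% suitability rather than recomputing
them from a series. The degraded-class constants are *not* proportional
to the palm densities (136/68/34 palms/ha would give 46/23/11.5), so no
series reproduces all three; fidelity to the established constants wins
for reproduction runs, and `reference_levels(series)` computes
proportional references when preferred.

## Discounted cash-flow models

One NPV core serves every model. Conventions, pinned jointly by the
requirement that a single rule set reproduce all eight coarse-model
values (37/103/202/409 upfront, 24/68/135/274 staggered):

* **End-of-year flows**: the year-*t* flow is discounted by $(1+r)^{-t}$,
  so even year-1 revenue is discounted one full period.
* **Annualisation**: NPV / 25 (plain division, not an annuity
  equivalent).
* **Reporting**: dollars round half away from zero; comparisons use
  unrounded values.
* **CO₂e factor**: exactly 3.67 as conventionally printed (not 44/12);
  fund cells only reproduce with 3.67.
* Negative net carbon yields negative revenue — no flooring — which is
  what makes REDD+ NPV negative in the 25 MgC/ha class under a full-stand
  reference.

**REDD+** cash flows: at price $p$ (USD/MgCO₂e) and net carbon $E$
(MgCO₂e/ha), the *upfront* stance pays $pE$ in year 1; the *staggered*
stance pays $pE/2$ in year 1 and spreads the remaining half evenly over
years 2–25. Costs are $25/ha establishment (year 1) and $10/ha running
(years 2–25). Prices default to {3, 7.8, 15, 30} (voluntary low/mid/high
and compliance), discount rates to {5, 8, 11, 14}% with 11% — the
regional industry rate — as the headline.

**Oil palm** (new plantings): yield ramps from immaturity (years 1–2 at
zero) to a 30 tFFB/ha peak in years 8–11, then declines linearly to
17 t/ha at year 25. The ramp increment, 44.5/15 t/yr over years 3–7, is
the unique linear ramp ending at the peak for which the 25-year mean is
exactly 21.92 t/ha/yr; degraded stands scale the curve by capacity (means
10.96 and 5.48). Revenue is a constant $178/tFFB. The per-year cost
schedule behind the published class NPVs is not public, so the package
ships a documented default: felling/ground preparation $1,214.8/ha in
year 1, harvesting and transport $33/tFFB (scales with crop), supplying
$0 by default (a mortality knob), and fixed general charges plus upkeep
of **$873.117348/ha/yr, calibrated so the full-stand model annualised at
11% equals the published $594/ha/yr benchmark**. The same schedule then
gives $128 and −$105/ha/yr at 50% and 25% capacity, close to (but not
forced onto) the published $129 and −$109; allocation therefore defaults
to the published benchmark thresholds {594, 129, −109} via
`oilpalm_npv_benchmarks()`, with the calibrated model available for
sensitivity work. One known tension is treated as rounding noise: at
$3/MgCO₂e the ≥350 MgC/ha class in medium-suitability areas computes to
$127/ha/yr against the $129 threshold, two dollars short of the
published break-even claim; the package does not adjust anything to force
that cell.

The **coarse model** is deliberately a thin wrapper: one fictitious
stratum (156 MgC/ha forest, 52 MgC/ha mature-palm reference) pushed
through the identical engine, so there is no second arithmetic path to
drift out of sync.

## Allocation

A stratum goes to REDD+ when its annualised REDD+ NPV is **equal or
higher** than the oil-palm NPV for its suitability class (ties to REDD+).
Roll-ups over the winning set report extent (and its share of the
landscape as a percentage rounded half away from zero), summed mid-point
carbon, CO₂e (carbon × 3.67, rounded once) and the funds needed
(price × *unrounded* CO₂e, rounded once) — the unique order of rounding
that matches every published fund cell, including the half-dollar case at
the compliance price.

## The synthetic generator

Because no plot or parcel data are released, the generator emulates the
inputs' statistical structure; all randomness flows from one seed and
regeneration is bit-identical.

* **Inventory**: 230 plots (110 ha total), Poisson stem counts, DBH
  log-normal truncated at the 10 cm measurement floor with median
  ≈ 25 cm (sdlog 0.5) — a plausible logged-forest structure chosen once,
  as the source distributions are unpublished; wood density uniform in
  (0.4, 0.8) g/cm³.
* **Landscape**: strata as abstract rows, not rasters — the analysis only
  needs (class × suitability × tenure × extent) bookkeeping. Class
  marginals default to the unprotected stock-table extents (30,173 ha);
  suitability marginals to 9,327 / 4,352 / 16,492 ha, which sum to
  30,171 — the source's own 2 ha mismatch, admitted by a 5 ha marginal
  tolerance. Each class extent is split proportionally to the suitability
  shares and then by tenure fractions (defaults proportional to the
  published tenure carbon shares), so class marginals hold exactly.
* **Palm series**: monotone per-palm accumulation (cumulative gamma
  increments, ≈0.6 MgC by age 19), surveyed at ages 2–19 minus
  configurable gaps. Palms younger than 2 years are treated as unsurveyed
  seedlings, which is what makes the default gap set reproduce the 11
  observed age categories.

What the generator does **not** emulate: spatial autocorrelation or real
geometry (suitability is independent of carbon class given the marginals,
whereas in reality flooding correlates with both), measurement error in
DBH, and the true joint class × suitability distribution, which is
unpublished. Passing tests therefore validate the accounting and
economics exactly, but landscape-level roll-ups on synthetic data are
structural analogues, not reproductions, of the published per-scenario
extents.

## Numerical choices and degenerate inputs

Gap completion is `stats::approx` with constant-value extrapolation,
which realises all three published completion rules at once. Truncated
log-normal DBH uses inverse-CDF sampling (no rejection loop). Empty
plots have density 0; empty landscapes and empty winner sets roll up to
zeros; degenerate density ranges collapse to a constant; `<2` palm
observations, all-gapped series, non-positive DBH/density/area, unknown
classes and vocabulary violations all raise errors rather than guessing.

## Interfaces

The package is a library: functions, `run_pipeline()` (flat CSV outputs
plus a JSON manifest with a config hash and per-file MD5s, logged
stage-by-stage to stderr) and `scripts/acceptance.R` form the interface;
no separate shell subcommand wrapper is shipped, since every stage is a
one-line function call.

## Problem sizes

All economics are closed-form 25-term sums; the full test suite runs a
230-plot inventory, landscapes of ~70 strata, and 8-scenario grids in a
few seconds.

## Known limitations

Above-ground carbon only (no soil or below-ground pools, which are large
in mangrove and peat systems); no timber revenue; FFB revenue rather than
milled CPO; no error propagation through the allometry; no spatial
optimisation of the winning set (strata are judged independently);
transaction costs beyond the establishment/running schedule are not
modelled.
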