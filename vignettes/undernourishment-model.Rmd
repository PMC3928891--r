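---
title: "Modelling undernourishment from food balance sheets: methods and design"
author: "PoUcast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling undernourishment from food balance sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PoUcast)
```

## The model

PoUcast implements the dietary-energy-deficiency approach to national food
security assessment: food deprivation is judged by comparing the
distribution of habitual dietary energy consumption (kcal/capita/day)
against a minimum energy requirement norm, and the prevalence of
undernourishment (PoU) is the mass of that distribution below the norm.

Three quantities pin the model down.

**Mean dietary energy supply (DES).** A food balance sheet (FBS) accounts
for each commodity's production, imports, exports, non-food uses and losses
(all tonnes/yr) and its energy density (kcal/kg). The DES is the energy of
the total net food supply divided by population and 365 days. We adopt the
standard FAO balance identity; stock changes are deliberately folded into
the losses column, since the accounting granularity here does not separate
them. The FBS is read as a national (or community) *supply* account. The
supply-vs-consumption distinction is a known tension in this methodology —
balance sheets measure availability, not intake — which is one reason the
projected prevalence should be read as *potential exposure* rather than
measured undernourishment.

**Inequality and the consumption distribution.** Consumption across the
population is modelled as lognormal — a unimodal, right-skewed law on
positive values, the conventional choice in this methodology. Two
parameterization decisions were genuinely open:

* *Location.* We fix the distribution's **arithmetic mean** to the DES
  (`muLog = log(meanDes) - sigma^2/2`), matching FAO practice, rather than
  setting the median to the DES. Under a median convention every reported
  PoU would shift; the mean convention conserves total energy.
* *Spread.* The Gini coefficient G of a lognormal obeys the exact identity
  G = 2Φ(σ/√2) − 1, so we invert it in closed form,
  σ = √2 · Φ⁻¹((G+1)/2), instead of using tabulated approximations. The
  inversion is exact to machine precision and round-trips to better than
  1e−9 (tested over 1,000 random spreads). A coefficient of variation can
  be supplied instead (σ = √ln(1+CV²)), retained for comparability with
  FAO publications; exactly one of the two must be given.

The supplied Gini is treated as the Gini of the *consumption distribution
itself*. Income Ginis are often what is published; where income and food
access inequality diverge, the user should transform before input.

**Minimum dietary energy requirement (MDER).** Per cohort, requirement =
BMR × PAL, with BMR linear in body weight. The coefficient table is
configuration, not code: `defaultBmrTable()` ships standard FAO/WHO/UNU
(Schofield) coefficients by age band and sex, and any table with the same
shape may replace it. The MDER is the count-weighted mean requirement across
cohorts. Because it is a *minimum* norm, reference weights should encode
minimum acceptable body mass and PAL a light-activity level; the package
does not separately model the FAO weight-for-height refinement or
children's growth allowance — both are absorbed into the per-cohort weight,
intercept and PAL configuration.

With σ from inequality and the cut-off M = MDER,

PoU = Φ((ln M − μ_log)/σ),  headcount = PoU × population.

## Scenario projection

A scenario evolves a *baseline* FBS under fractional deltas: yield deltas
applied to production separately for C3- and C4-photosynthesis commodities
(the C3/C4 split is a per-commodity input label, not a hardcoded crop list),
and a trade delta applied to imports and exports. Three structural rules:

* **Baseline-anchored deltas.** Year-t deltas are applied to the baseline
  sheet, never compounded on year t−1; each projected year is independent
  of the others.
* **Held at baseline.** Non-food uses and losses keep their absolute
  baseline values; the age–sex structure, the Gini and the MDER are scalar
  fields of the scenario and cannot vary by year; the trade delta defaults
  to zero for every year, so imports and exports stay at baseline unless
  explicitly overridden.
* **Annual resolution.** Population trajectories and delta series supplied
  at coarser steps (e.g. decadal climate time slices) are linearly
  interpolated to years — the simplest monotone choice — and never
  extrapolated outside their range.

These rules make the output an indicator of potential exposure: the model
asks what undernourishment would look like if drivers changed but behaviour,
trade policy and demography did not respond.

## Numerical choices

* Units are fixed internally: tonnes/yr for mass, kcal/kg for energy
  density, kcal/capita/day for DES and MDER; the tonne→kg factor 1000 and
  the 365-day year are applied inside `dietaryEnergySupply()`.
* A negative *net* supply is legal at the record level (re-exports exceed
  production in odd years) but an error at DES time, reported with the
  offending commodity; inside a projection the error is annotated with the
  failing year.
* Deltas ≤ −1 (a −100% change or worse) are rejected at the argument level.
* Headcounts round half-up to whole persons (`floor(x + 0.5)`), not to even,
  so printed headcounts always recover `pou × population` to ±0.5 persons.
* Projection files print fractions with 6 decimals, energies with 1 and
  persons as integers, making outputs byte-stable for golden-file tests.
* Degenerate inputs: a sheet needs ≥ 1 commodity; MDER needs positive total
  population; a trajectory of length 1 is constant; `gini` is confined to
  the open interval (0,1) and `sigma`, `cv` to (0,∞).

## The synthetic generator

`synthConfig()` fixes the demo study conditions: 12 commodities with C4
share 0.6, baseline DES 2200 kcal/capita/day, Gini 0.30, a population of
13.1 million growing 2.9%/yr over a 50-year horizon, and C4 yields declining
linearly to −37.5% of baseline at the final year (the midpoint of the
35–40% mean reduction projected for maize under high-emissions climate
scenarios), with C3 and trade deltas zero. These values emulate a
maize-dependent low-income country under rapid population growth; the
generated projection reproduces the qualitative pattern of interest — a
steep post-baseline rise in undernourishment driven jointly by population
growth and C4 yield decline, with a 4.18-fold (1.029⁵⁰) population ratio —
without claiming to reproduce any published national curve, since the
underlying crop-model and demographic inputs of such curves are not
deposited anywhere we can draw on.

The generator calibrates the balance sheet so the baseline DES hits its
target exactly (energy shares are drawn, then net supplies are solved for;
trade and loss fractions are drawn and production back-solved, keeping the
balance identity exact). Cohorts get a young-skewed pyramid, asymptotic
weight growth toward a minimum-acceptable adult weight (~52 kg) and
light-activity PAL in [1.4, 1.6] — appropriate for a *minimum* requirement —
yielding an MDER near 1800 kcal/capita/day. Counts are apportioned by
largest remainder so they sum exactly to the configured population.

What the generator does **not** emulate: commodity-level trade flows,
within-country heterogeneity, seasonality, price responses, changing age
structure, or any crop/climate simulation. Passing tests on synthetic data
therefore demonstrate the *computational* correctness and the qualitative
scenario behaviour of the pipeline, not predictive skill on real data.

## Validation design

The closed-form PoU is checked against an independent Monte Carlo route: the
empirical fraction of 10⁶ lognormal draws below the cut-off, over a 5×5×5
grid spanning DES 1600–3000, Gini 0.15–0.55, MDER 1400–2100, with a
per-cell tolerance of 3 binomial standard errors √(p(1−p)/n). One caveat is
worth stating precisely: with 125 independent cells, the probability that
*some* cell exceeds 3 SE by pure sampling noise is 1 − 0.9973¹²⁵ ≈ 29%,
even when the analytic form is exactly right. Across 30 validation seeds we
observed max per-cell deviations between 2.0 and 4.0 SE, with 27% of seeds
exceeding 3 SE somewhere — exactly the no-multiplicity-control expectation.
The validation suite therefore reports the maximum deviation in SE units
alongside the per-cell pass flags (`validatePou()`, CLI `validate`), and a
marginal exceedance (3–4 SE in one cell of 125) should be read as sampling
noise, not as evidence against the closed form; gross errors would appear
as many cells failing at once, which is additionally guarded in the test
suite. Under the default validation seed the maximum deviation is 3.02 SE
in a single cell.

Further checks: MDER equals a brute-force weighted accumulation on 200
random cohort tables to 1e−9 relative error; identity scenarios are exactly
constant; headcount/population recovers PoU at every year; and re-estimating
the mean and empirical Gini from 10⁶ raw draws recovers the generating PoU
within 0.005.

## Problem sizes

The shipped tests and the reproduction script use 10⁶ draws per Monte Carlo
cell, 125 grid cells, 1,000 inversion round-trips, 200 random cohort tables,
100 end-to-end generator seeds and a 51-year projection horizon — sizes at
which every stochastic tolerance above is comfortably resolved on a single
CPU in a few minutes.

## Known limitations

* The lognormal is fixed by design; no skew-normal or log-logistic
  alternatives.
* National aggregation only: no intra-household allocation, no
  beneficiary-level disaggregation.
* Scalar trade deltas; no trade-flow model between regions.
* Projections hold inequality, requirements and demography at baseline, so
  long-horizon output is an exposure indicator, not a forecast.
* Aggregated agricultural statistics can be substantially wrong in exactly
  the settings where this methodology is most used; the model propagates,
  and cannot correct, biased balance sheets.
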