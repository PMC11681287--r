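---
title: "Estimating ambulance and ED demand from sparse survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ambulance and ED demand from sparse survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsdemand)
```

## The estimation problem

Many large cities in low- and middle-income settings have no unified EMS
record: ambulance providers are fragmented, hospitals do not record arrival
mode, and official health reports stop at hospital attendance. emsdemand
implements a transparent way to estimate annual ambulance needs per
neighborhood from what *is* obtainable — a patient-arrival survey at a few
hospitals, annual ED volumes from a hospital sample, and official population
and commuter statistics.

The expected annual number of ambulance-borne ED arrivals from neighborhood
$i$ in period $j$ is

$$ D_{ij} = P_{ij}\,\varepsilon_j\,\lambda\,\delta_i , $$

with $P_{ij}$ the period population, $\varepsilon_j$ the probability an
emergency falls in period $j$, $\lambda$ the annual per-capita ED visit
rate (assumed uniform across the city), and $\delta_i$ the ambulance-use
proportion. City totals sum over neighborhoods and periods; dividing an
ambulance total by the pooled usage rate (ambulance users over all surveyed
patients) converts it to total emergency-care need. The model's key
assumptions are independence of patients, a city-uniform $\lambda$, and
time-homogeneity within each 12-hour period.

## Parameters, defaults and units

| Parameter | Meaning | Default | Unit |
|---|---|---|---|
| `base_population` | nighttime residents | 10,500,000 | persons |
| `commuter_net_inflow` | signed net daytime inflow per municipality | 1,100,000 total | persons |
| `true_day_share` | day-period arrival probability (generator) | 0.625 | probability |
| `true_ambulance_rate` | ambulance-use probability (generator) | 0.093 | probability |
| `survey_n` | surveyed patients | 1964 | records |
| `n_hospitals_with_ed` | ED-equipped hospitals the sample scales to | 86 | hospitals |
| `n_replicates` | bootstrap replicates | 10,000 | replicates |
| `conf_multiplier` | normal CI critical value | 1.96 | — |
| `usage_rate` | conversion to total emergency care | pooled survey rate | probability |

Day is 06:00–17:59 and night 18:00–05:59. Timestamp classification uses
half-open intervals — 06:00:00 exactly is day, 18:00:00 exactly is night —
so no arrival is double-counted at the boundaries.

Per-capita rates are kept at full precision in the demand arithmetic;
`use_rounded_rates = TRUE` switches to the two-decimal labels (0.10, 0.20,
0.29 on the default hospital summary) for reproducing published-style
tables, whose arithmetic was done on rounded rates. The high scenario takes
the third quartile (0.29 after rounding); the derived city totals imply the
sample's unrounded median and Q3 are 24,628.5 and 35,729.5, which is what
`jakarta_ed_summary()` stores.

## What the synthetic generator emulates — and what it does not

`generate_registry()` reproduces the administrative skeleton (5
municipalities with 8/6/8/10/10 districts and 44/31/56/65/65 neighborhoods)
and conserves the aggregate population identities exactly: nighttime
populations sum to the base population and daytime to base plus net inflow,
via largest-remainder integerisation. Since per-neighborhood census figures
are not published, within-district population shares are drawn from a
symmetric Dirichlet law with concentration 50 — neighborhoods of a district
are then comparable in size (coefficient of variation about
$1/\sqrt{50} \approx 14\%$), matching the premise that areas within a
district share population characteristics. Commuter inflows are allocated
within a municipality proportionally to nighttime population, because only
municipality-level commuting totals are published; the split across the
three municipalities not individually reported (158,000 of the 1.1 million
after Central's 524,000 and South's 418,000) is a fixed package choice.

`generate_survey()` assigns patients to neighborhoods proportionally to
daytime population (ED attendance scales with the exposed population in the
demand model) and draws period and ambulance flags as independent
Bernoullis. `generate_hospital_volumes()` draws log-normal volumes
(meanlog $\log 24629$, sdlog 0.95), a right-skewed law whose 10-draw
samples typically span the low thousands to tens of thousands of visits.

What the generator does **not** emulate: spatial correlation between
neighboring areas, any systematic variation of the true ambulance-use rate
with neighborhood size or wealth, transport modes other than
ambulance/other, and seasonality. In the original survey the unweighted mean
of neighborhood proportions (≈0.074) fell well below the pooled rate
(0.093), implying such heterogeneity in the real data; under the generator's
default *uniform* true rate all three estimators are centred on 0.093.
Passing tests on synthetic data therefore demonstrates the correctness of
the estimators' arithmetic and their distributional properties, not that the
generator reproduces the real survey's between-neighborhood structure. Where
a published-scale δ is needed (scenario-band checks), the published rates
are supplied as explicit inputs rather than re-estimated.

## The three δ estimators

The **naive** estimator is the unweighted mean of the per-neighborhood
observed proportions; the **weighted naive** estimator weights them by
daytime-population share. Sample-size weights were deliberately not used:
they would collapse the estimator onto the pooled rate, whereas
population weights keep it close to the unweighted mean when populations are
near-uniform — the relationship the published estimates (0.07403 vs 0.07406)
exhibit. Neighborhoods with no surveyed patients are excluded from
estimation and receive the city-level δ in demand computation.

The **Monte Carlo** estimator is a parametric binomial bootstrap: each
replicate redraws every surveyed neighborhood's ambulance count from
$\mathrm{Binomial}(n_i, \hat p_i)$ and records the unweighted mean of the
resampled proportions. This is the simplest resampling mechanism consistent
with drawing random samples from each neighborhood's observed distribution.
The estimate is the mean of replicate means; because the replicate means are
an average over hundreds of independent areas, the central limit theorem
justifies the normal-approximation CI
$\hat\delta \pm 1.96\,\mathrm{sd}/\sqrt{R}$. The bootstrap is mean-unbiased
— $E[\hat p_i^{(r)}] = \hat p_i$ — so its delta converges to the naive value
as $R \to \infty$; the test suite asserts agreement within 4 Monte Carlo
standard errors at $R = 10{,}000$. `compare_to_reference()` runs the
one-sample, two-sided t-test of the replicate means against each naive
value, reported separately per reference.

## Numerical choices

- **Integerisation**: largest-remainder (Hamilton) allocation everywhere an
  integer total is split proportionally, so population identities hold
  exactly; ties in fractional remainders break toward the larger weight.
- **Rounding**: aggregates are rounded half-away-from-zero, and only at
  report time — per-row rounding would break the additivity
  (night + day = total) that the output tables display.
- **Quantiles**: linear interpolation between order statistics
  (`stats::quantile` type 7); for even $n$ the median is the mean of the two
  central values.
- **Degenerate inputs**: a survey with zero ambulance users yields a
  zero-width CI and a defined δ of 0, but the t-test is refused with an
  explicit degenerate-distribution error rather than returning NaN; the
  pipeline records the comparison as unavailable and warns.
- **Seeds**: every stochastic function takes a `seed` and restores the
  caller's RNG state, so identical configurations are byte-identical and
  composable.

## Problem sizes

The default study conditions are used throughout: 261 neighborhoods, 1964
survey records, 10 hospitals, 10,000 bootstrap replicates. Property-style
checks (population conservation, CI coverage, rate recovery) use 200
replicate draws at reduced per-survey sizes, which gives standard errors
small enough to detect biases of a fraction of a percentage point.

## Limitations

Exact reproduction of published per-neighborhood day/night splits is
impossible without the unpublished per-neighborhood census and survey count
tables; the package instead verifies the closed-form aggregate (within 0.5%
at matched city totals), the additive and conversion identities, and the
estimators' statistical properties. No fleet sizing, location-allocation,
queueing or response-time modelling is included — the output is annual
expected demand, the input such planning models need.
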