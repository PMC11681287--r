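# emsdemand

Small-area estimation of annual ambulance needs and hospital
emergency-department (ED) visits for a city where no aggregated emergency
medical services (EMS) data are collected. The package is aimed at health
services researchers and capacity planners who must piece a demand estimate
together from a patient survey, a small hospital sample, and official
population and commuting statistics — the situation in Jakarta, the
motivating setting, whose administrative structure (5 municipalities, 42
districts, 261 mainland neighborhoods, 10.5 million residents, 1.1 million
net daytime commuters) is the default synthetic city.

## The model

Let `P_ij` be the population of neighborhood `i` in period `j` (day =
06:00–17:59, night = 18:00–05:59), `ε_j` the probability that an emergency
falls in period `j`, `λ` the annual per-capita ED visit rate, and `δ` the
proportion of ED arrivals that came by ambulance. The expected annual
ambulance-borne ED arrivals are

```
ambulance need = Σ_i Σ_j  P_ij · ε_j · λ · δ_i
```

and dividing an ambulance total by the pooled ambulance-usage rate (the
fraction of all surveyed ED patients who used an ambulance) converts it into
total emergency-care need. The four parameters are estimated as:

- **`P_ij`** — nighttime populations from the registry; daytime populations
  add each municipality's net commuter inflow, distributed over its
  neighborhoods proportionally to nighttime population
  (`split_day_night_population()`).
- **`ε_j`** — the observed day/night share of surveyed arrival times
  (`estimate_period_probabilities()`).
- **`λ`** — low/mid/high scenarios from the quartiles of a hospital ED-volume
  sample, scaled to all ED-equipped hospitals and divided by the population
  (`estimate_per_capita_scenarios()`).
- **`δ`** — three estimators on the per-neighborhood survey counts
  (`naive_rate()`, `weighted_naive_rate()`, `monte_carlo_rate()`); the Monte
  Carlo estimator is a parametric binomial bootstrap that redraws each
  neighborhood's ambulance count from Binomial(n, observed proportion),
  yielding a replicate-mean distribution, a normal-approximation 95% CI, and
  a one-sample t-test against the naive values (`compare_to_reference()`).

## Worked example

```r
library(emsdemand)

reg    <- generate_registry(city_template(), seed = 1)  # 261 neighborhoods
svy    <- generate_survey(reg, seed = 2)                # 1964 patient records
counts <- aggregate_survey(svy)

estimate_period_probabilities(svy)
#> <period_probs> day 0.620 (n=1218) | night 0.380 (n=746)

mc <- monte_carlo_rate(counts, n_replicates = 10000, seed = 3)
mc
#> <ambulance_rate_estimate> method: simulation | delta = 0.07525
#>   (95% CI 0.07514-0.07536, 10000 replicates) | 261 neighborhoods

scenarios <- estimate_per_capita_scenarios(jakarta_ed_summary())
tab <- build_scenario_table(reg, estimate_period_probabilities(svy), scenarios,
                            list(naive_rate(counts),
                                 weighted_naive_rate(counts, reg), mc),
                            usage_rate = pooled_rate(counts))
dplyr::select(tab, method, rate_label, night_total, day_total,
              ambulance_total, emergency_care_total)
#> # A tibble: 9 × 6
#>   method         rate_label night_total day_total ambulance_total emergency_care_total
#> 1 naive          low              30782     55523           86305              1066060
#> 2 weighted_naive low              31476     56775           88251              1090099
#> 3 simulation     low              30782     55523           86305              1066062
#> 4 naive          mid              60543    109204          169747              2096747
#> ...
```

The nine rows cross the three per-capita scenarios (Q1/median/Q3 of the
hospital sample, i.e. λ ≈ 0.10/0.20/0.29 visits per person-year) with the
three δ estimators. `night_total`/`day_total` are expected annual
ambulance-borne ED arrivals by period, `ambulance_total` their sum, and
`emergency_care_total` the implied total annual ED visits after dividing by
the pooled usage rate. Here the simulation delta (0.07525) sits on top of
the naive value, as the binomial bootstrap is mean-unbiased; with a
city-wide true rate of 9.3% the estimators land near 0.075–0.077 for this
survey draw.

`run_pipeline(pipeline_config(seed = 1))` runs all stages end to end and
writes the CSVs, a JSON manifest and (via `render_report()`) a markdown
report with a density plot of the replicate means.

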