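# pcdea

Output-oriented DEA benchmarking of municipal primary health care.

## The problem

Municipal managers allocate scarce primary-care resources — physicians,
nurses, basic health units and their equipment — and are accountable for
what those resources produce: home visits, prenatal and nursing
appointments, vaccination, and ultimately birth and hospitalization
outcomes. `pcdea` benchmarks each municipality against an empirical
best-practice frontier built from its peers of similar population size,
identifies the reference municipalities whose input/product mix others
could emulate, and quantifies how much more each inefficient municipality
would need to produce to reach the frontier. It is written for health-
services researchers and evaluation teams working with municipal
indicator tables (one row per municipality).

## The model

Each municipality is a decision-making unit (DMU) with input vector
`x₀` and output vector `y₀`. Efficiency is measured with the
output-oriented Banker–Charnes–Cooper (BCC) envelopment model under
variable returns to scale: the largest equiproportional expansion factor
φ of the DMU's outputs attainable by a convex combination of observed
DMUs that uses no more of any input,

```
max φ   s.t.   Σⱼ λⱼ xᵢⱼ ≤ xᵢ₀  (every input i)
               Σⱼ λⱼ yᵣⱼ ≥ φ yᵣ₀ (every output r)
               Σⱼ λⱼ = 1,  λⱼ ≥ 0
```

The efficiency score is 1/φ ∈ (0, 1]; φ = 1 means the DMU is on the
frontier. A second phase fixes φ* and maximizes total slack, so reported
peer (reference) sets come from a maximal-slack optimum and are
deterministic. The linear programs are solved by an in-package two-phase
primal simplex with Bland's rule.

Two companion models ship built in: a **health-actions model**
(4 inputs, 4 products) and an **outcomes model** (3 inputs, 2 outcome
percentages), both augmented with per-capita *control products* (rates
per 1,000 inhabitants, equipment percentages) that stop a municipality
with deficient inputs from looking efficient through scarcity alone.
Controls are omitted for municipalities of up to 5,000 inhabitants. The
preprocessing chain applies the evaluation's homogenization rules:
participation and 80%-coverage exclusions, consistency checks,
zero-input removal, 5th/95th-percentile trimming of per-capita rates,
and stratification into five population-size classes.

## Worked example

Generate synthetic municipalities with a planted Cobb–Douglas frontier
and known true efficiency, preprocess them for the health-actions model,
and estimate the frontier of the 10–20k-inhabitant stratum on the raw
products:

```r
library(pcdea)

gen  <- generate_municipalities(synthetic_config(
          n_per_stratum = c(`3` = 120), seed = 42))
spec <- builtin_model_specs()$model1
spec$controls_omitted_strata <- 1:5      # raw-product frontier
pre  <- preprocess_model(gen$table, spec)
fr   <- dea_frontier(pre$strata[["3"]])
glance(fr)
#>   stratum     n n_efficient n_inefficient pct_inefficient mean_score min_score
#> 1       3    72          33            39            54.2      0.886     0.485
```

Of the 120 generated records, 72 survive the exclusion and trimming
stages; 39 of them (54.2%) sit below the frontier. The least efficient
municipality would have to double its production:

```r
td <- tidy(fr)
head(td[order(-td$phi), c("dmu_id", "phi", "score", "reference_count")], 3)
#>   dmu_id   phi score reference_count
#> 1 M0109   2.06 0.485               0
#> 2 M0020   1.90 0.525               0
#> 3 M0065   1.80 0.556               0
```

`phi = 2.06` means every product must expand by 106% (score
1/φ = 0.485) for M0109 to reach its peers' frontier. Aggregating the
radial targets over all inefficient DMUs gives the stratum's production
shortfall per product:

```r
ex <- aggregate_expansion(fr)
ex[ex$stratum == "total", c("product", "shortfall", "observed_total", "pct")]
#>   product               shortfall observed_total   pct
#> 1 home_visits               7826.          58283  13.4
#> 2 nursing_appointments     18347.         138100  13.3
#> 3 prenatal_appointments     3689.          27908  13.2
#> 4 vaccine_third_dose        1573.          11512  13.7
```

i.e. home visits across the stratum would need to rise by 13.4% (≈7,800
visits) for every municipality to operate efficiently.
`classify_dmus(fr)` splits the 33 efficient units into benchmarks
referenced by other municipalities (26, `efficient_multi_reference`) and
units efficient only for themselves (7), and `cross_classify()` joins
the two models' classifications into the six-category contingency
table. `run_pipeline(run_config(...))` chains every stage and writes
the report CSVs.

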