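# skinqspr

Quantitative structure–permeability relationship (QSPR) modelling of the
human skin permeability coefficient, for formulation scientists, dermal
risk assessors and anyone who needs a log *K*p estimate for a compound
that has never been through a Franz cell.

The permeability coefficient *K*p (cm/s) measures how readily a compound
crosses human skin from an aqueous vehicle at steady state. Curated
permeation databases report log10 *K*p together with the experimental
conditions of each measurement — anatomical skin source, the skin layer
mounted, whether the donor solution was saturated ("neat") or diluted,
and the donor temperature. Those conditions move the measured values
substantially, so this package stratifies the data before modelling
instead of pooling everything.

The model at the core is ordinary least squares on three 2D molecular
descriptors:

    logKp = b0 + b1·logP + b2·TPSA + b3·MV

with logP the octanol–water partition coefficient, TPSA the topological
polar surface area (Å²) and MV the molecular volume (Å³). The pipeline:

1. **Read & validate** permeability and descriptor tables
   (`read_permeability_table()`, `read_descriptor_table()`), excluding
   records with unspecified experimental conditions
   (`filter_complete()`).
2. **Stratify** records into the 3 × 4 × 2 × 4 = 96 experimental
   scenarios (`enumerate_scenarios()`, `assign_scenarios()`).
3. **Fit** one QSPR per non-empty scenario (`build_scenario_table()`,
   built on `fit_qspr()`), **select** the best model subject to a
   minimum-size floor (`select_best()`), and **validate** it with a
   seeded 80/20 train/test split that guarantees descriptor coverage
   (`split_train_test()`).
4. **Pool** alternatively: reduce to one *K*p per compound by scored
   experimental-preference criteria, remove |residual| > 1.5 outliers in
   a single pass and refit (`run_pooled_workflow()`).
5. **Predict** with your own fits or with the shipped published
   equations — 27 per-scenario models, the best-scenario and pooled
   equations, and a Potts–Guy-style logP/MW baseline
   (`published_models()`, `predict_published()`, `predict_potts_guy()`).

A synthetic-data generator with exact ground-truth bookkeeping
(`generate_dataset()`, `make_table1_like()`) makes every stage testable
without downloading anything.

## Worked example

Fit per-scenario models on a realistically shaped synthetic dataset,
pick the best one and validate it:

```r
library(skinqspr)

ds         <- make_table1_like(seed = 42)      # 342 records, 27 scenarios
kept       <- filter_complete(ds$records)$kept
assignment <- assign_scenarios(kept, ds$descriptors)
tab        <- build_scenario_table(assignment)
best       <- select_best(tab, min_n = 16)
best
#> QSPR model (fitted, abdomen/dermis/diluted/20-25): logKp = -3.933 + 0.934 logP + 0.015 TPSA - 0.021 MV
#>   n = 16, R^2 = 0.9938, RMSE = 0.2935 [log10(cm/s)]

split_train_test(assignment$groups[[best$scenario]], seed = 42)
#> Train/test validation
#>   logKp = -4 + 0.922 logP + 0.016 TPSA - 0.021 MV
#>   training set: n = 13, R^2 = 0.9938, RMSE = 0.3107
#>   test set:     n = 3, R^2 = 0.9804, RMSE = 0.2287
#>   seed = 42, resample attempts = 2
```

`select_best()` returned the scenario with the highest R² among those
fitted on at least 16 rows; the split refits on the training rows only
and reports both partitions' R² and RMSE (log10 units), so the test-set
line is the honest estimate of predictive performance.

Predicting for a new compound from the published equations:

```r
# the published model for abdominal epidermis, diluted donor, 22 °C
lookup_published("abdomen", "epidermis", "diluted", 22)
#> QSPR model (published, abdomen/epidermis/diluted/20-25): logKp = -6.052 + 0.777 logP - 0.004 TPSA - 0.008 MV
#>   n = 36, R^2 = 0.8545, RMSE = NA [log10(cm/s)]

# best-scenario equation for logP 1.5, TPSA 40 Å², MV 220 Å³
predict_published("eq2", data.frame(logp = 1.5, tpsa = 40, mv = 220))
#> [1] -6.649

# two-descriptor baseline (logP, molecular weight), as published
predict_potts_guy(1.5, 180)
#> [1] -6.333
```

The first prediction says the compound is expected to cross at
log *K*p ≈ −6.6, i.e. *K*p ≈ 2 × 10⁻⁷ cm/s — a slow permeant.

A command-line front end wraps the same functions
(`inst/scripts/skinqspr`): subcommands `simulate`, `fit-scenarios`,
`fit-pooled`, `predict` and `validate`, each writing its outputs plus a
JSON run manifest.

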