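# tractprev

Small-area estimation of chronic respiratory illness prevalence — asthma and
COPD — at US census-tract resolution, from features derived from search-query
logs, optionally combined with land-cover and census demographic features.

Tract-level prevalence surveys are costly and infrequent, yet tract-scale
(neighborhood-scale) prevalence maps are what lets local health agencies
target interventions. Search queries offer a continuously available,
near-complete geographic signal: people affected by an illness search for its
symptoms, medications and related information. `tractprev` implements that
estimation pipeline for researchers in digital epidemiology and small-area
estimation, together with a synthetic-city generator that emulates all four
input sources (tract geometries, demographics, a categorical land-cover
raster, and a geo-located query log), so the full method is reproducible and
testable without any proprietary or downloaded data.

## Method

For tract *i* with query set *Q<sub>i</sub>* and keyword *k*, the core
feature is the normalized count

> *S<sub>i</sub>(k)* = |{q ∈ Q<sub>i</sub> : k ∈ q}| / |Q<sub>i</sub>|

smoothed over the *m* nearest tracts (Euclidean centroid distance, self
included; default *m* = 8):

> *Ŝ<sub>i</sub>(k)* = Σ<sub>j ∈ N<sub>m</sub>(i)</sub> S<sub>j</sub>(k) / *m*

Keywords are found by training a skip-gram embedding (*d* = 100, window
*w* = 6) on the query corpus, ranking the vocabulary by cosine similarity to
the seed terms *asthma*, *copd*, *smoking*, keeping the maximal top-ranked
prefix of disease-related terms, and adding a curated medication list.
Per-category sums (symptoms, diseases, medications) address sparsity.
Optional context features: 20 land-cover class proportions, three
pixel-adjacency statistics, 20 census proportions (9 age, 2 gender, 8 race,
1 poverty; never smoothed), and an integer-coded state.

A seeded random-forest regressor maps features to prevalence (percent).
Evaluation is 5-fold cross-validation scored by Pearson correlation and mean
absolute error of pooled out-of-fold predictions; feature importances are
node-purity (impurity-decrease) values. Tracts with missing census or
land-cover data, or fewer than 50 distinct users in the log, are excluded.

## Worked example

```r
library(tractprev)

city <- simulate_city(n_tracts = 500, seed = 1)   # the reference conditions
city
#> <synthetic_city> seed 1
#> <tract_set> 500 tracts, 4 states, region 35.00 x 35.00 km
#> <query_log> 2037682 events, 101920 users, 500 tracts, 8318249 tokens

flt <- filter_tracts(city$tracts, city$queries, city$census, city$landcover)
table(flt$ledger$reason)
#> under_privacy_threshold
#>                       3

report <- run_experiment(experiment_config(city))
report
#> <experiment_report> 497 tracts retained, 3 excluded
#>             variant outcome correlation      mae
#>              search  asthma   0.6072929 1.464390
#>              search    copd   0.6362269 1.356105
#>        search_state  asthma   0.6474051 1.407300
#>        search_state    copd   0.6988673 1.261338
#>         search_land  asthma   0.6087495 1.459078
#>         search_land    copd   0.6375753 1.353980
#>  search_land_census  asthma   0.7536125 1.274818
#>  search_land_census    copd   0.7675620 1.164582
```

Three tracts fall below the 50-distinct-user privacy threshold and are
excluded. Reading the table: the query-only model (`search`) recovers the
spatial pattern of prevalence at r ≈ 0.61–0.64 with a mean absolute error of
about 1.4 percentage points (against outcome means of 9.783% and 6.416%);
adding the state code, and then land-cover plus census features, raises the
correlation to ≈ 0.75–0.77 and drops the error — each added data source
improves the fit, with the all-source model best. Top query predictors of the COPD
model:

```r
head(report$cv$search$copd$importances, 5)
#>   rank         feature importance
#> 1    1    sum_symptoms  333.51685
#> 2    2    sum_diseases  155.39063
#> 3    3          vaping   74.53975
#> 4    4 sum_medications   69.51191
#> 5    5        rhinitis   63.06978
```

The keyword-selection stage is available separately:

```r
model  <- train_embedding(city$queries, d = 100, w = 6, seed = 1)
ranked <- rank_by_similarity(model)        # seeds: asthma, copd, smoking
head(ranked, 3)                            # most illness-like terms first
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/tractprev.R simulate --out city/ --seed 1
Rscript inst/cli/tractprev.R run --dir city/ --out results/ --seed 1
```

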