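---
title: "Estimating tract-level respiratory illness prevalence from search-query features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tract-level respiratory illness prevalence from search-query features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Census tracts are the smallest US geographic unit with published demographic
data — roughly 4,000 inhabitants each. Survey-based tract-level estimates of
chronic disease prevalence (such as the CDC's 500 Cities estimates for asthma
and COPD) are expensive and infrequent. `tractprev` implements an
alternative: estimate tract prevalence from the population's search behavior,
on the premise that residents affected by an illness search for its symptoms,
medications and related information more often than others.

The pipeline has four stages:

1. **Keyword expansion.** A skip-gram word embedding is trained on a query
   corpus; the vocabulary is ranked by cosine similarity to seed illness
   terms (`asthma`, `copd`, `smoking`) and keywords are taken as the maximal
   top-ranked prefix whose terms are all judged disease-related, augmented
   with a curated medication list.
2. **Feature construction.** For keyword $k$ and tract $i$, the normalized
   count $S_i(k) = |\{q \in Q_i : k \in q\}| / |Q_i|$ is the fraction of
   tract $i$'s queries containing $k$. Per-category sums (symptoms,
   diseases, medications) address sparsity, and each query and land-cover
   feature is smoothed over the $m$ nearest tracts (self included, Euclidean
   centroid distance): $\hat S_i(k) = \sum_{j \in N_m(i)} S_j(k) / m$.
   Optional context features: per-tract land-cover class proportions, three
   pixel-adjacency statistics (developed-next-to-developed,
   developed-next-to-forest, forest-next-to-forest), 20 census proportions
   (9 age, 2 gender, 8 race, 1 poverty), and an integer-coded state.
3. **Estimation.** A seeded random-forest regressor is evaluated by k-fold
   cross-validation; performance is the Pearson correlation and mean
   absolute error (percentage points) of pooled out-of-fold predictions.
   Importances are node-purity (impurity-decrease) values.
4. **Filtering.** Tracts lacking census or land-cover data, or with fewer
   than 50 distinct users in the query log, are excluded up front (the
   privacy threshold mirrors the data-governance rule of the real query
   data).

Because the real inputs (a proprietary query log, CDC/NLCD/ACS extracts)
cannot ship with a package, a synthetic-city generator produces inputs with
the statistical structure this method assumes, making every stage testable
end to end.

## The synthetic city

`simulate_city()` chains five generators under one master seed:

* `generate_tracts()` tiles a square region into trapezoids (jittered
  rectangular tiling, exact by construction), with contiguous state blocks
  and log-normal populations. Defaults match the scale of urban US tracts:
  median area 2.45 km², median population 3652.
* `generate_census()` draws the 20 demographic proportions from symmetric
  Dirichlet distributions within each block (age, gender, race) plus a
  uniform poverty share. The symmetric form was chosen so the concentration
  parameter has the simple limit "large = homogeneous tracts"; non-uniform
  expected profiles are available via `block_means`.
* `generate_landcover()` assigns each raster cell one of the 20 NLCD
  sub-classes by the Gumbel-max rule on per-class noise fields; `clumping`
  box-blurs the fields to create spatially coherent patches. At
  `clumping = 0` this is exact i.i.d. categorical sampling.
* `generate_prevalence()` builds each outcome as
  `clip(base + X beta + state offset + noise, 0, 100)` over census and
  land-cover features. Default bases are the national tract-level means:
  9.783% (asthma) and 6.416% (COPD). Default effects encode poverty and
  dense development raising asthma, and poverty plus old age raising COPD;
  state offsets are N(0, 1.5²) percentage points, noise N(0, 1²).
* `generate_queries()` gives each tract
  `max(1, round(users_per_capita * population))` users issuing
  Poisson(`queries_per_user`) queries of Zipf-weighted background words.
  With probability `base_rate * (1 + signal_strength * prevalence_i / 100)`
  a query carries `1 + Poisson(0.35)` disease keywords drawn by category
  mix. The extra co-inserted keywords model users searching several related
  terms at once; they are what gives the embedding its co-occurrence signal.

Reference conditions (the defaults): 500 tracts, 4 states, 5% of residents
issuing on average 20 queries each, `signal_strength = 2`, `base_rate = 0.05`.

What the generator deliberately does **not** emulate: real geography
(lon/lat, shapefiles), reverse-IP geolocation error (events carry exact
tract assignments; a point-in-polygon utility covers coordinate inputs),
temporal query dynamics, query grammar (tokens are bags of words), and the
demographics of internet use. The last point matters for interpretation:
passing recovery tests show the estimator works when the query signal is
present and unconfounded; they cannot show robustness to differential
internet penetration, which no query-based estimator can rule out
without knowing who contributes the queries.
`users_per_capita` is a single knob — no stance is taken on its real-world
dependence on poverty.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| embedding dimension `d` | 100 | common skip-gram choice for query text |
| context window `w` | 6 | a typical query length |
| training `epochs` / `min_count` | 5 / 5 | standard word2vec defaults, overridable |
| seed aggregation | max over seeds | a term strongly tied to any one illness qualifies; mean available |
| smoothing window `m` | 8 | best-performing window for query features; swept over {1, 4, 8, 16, 32} by `sweep_m()` |
| privacy threshold | 50 users | data-governance rule; tracts at 49 are excluded, at 50 retained |
| forest size / mtry / min leaf | 500 / ⌈p/3⌉ / 5 | regression-forest conventions |
| CV folds | 5 | matches the evaluation design |

## Numerical and design choices

* **Distances** are Euclidean on planar km coordinates — the synthetic
  region is desk-scale and the neighbor definition is metric-agnostic.
  Neighbor ties break lexicographically by tract id, making indexes
  deterministic.
* **Keyword matching** is exact token membership, not substring: substring
  matching would conflate short terms with unrelated strings, and token
  matching is deterministic for tests.
* **Pixel adjacency** uses the 4-neighborhood (von Neumann) by default with
  the 8-neighborhood as an option; grid-edge neighbors count as non-target.
* **Zero denominators** (a tract with no queries; no focal pixels of a
  class) yield 0 plus a flag attribute rather than NA, keeping the design
  matrix complete while surfacing sparsity. A tract capturing no raster
  cell centers gets region-wide mean proportions and a degenerate flag.
* **Boundary points** in point-to-tract assignment go to the
  lexicographically smallest owning tract.
* **The m-sweep** scores training-data fit (it diagnoses how much spatial
  averaging the raw counts need), while model comparison always uses
  held-out folds; the two are computed by separate code paths and labelled.
  Under the default desk-scale conditions per-tract counts rest on
  thousands of queries, so raw features (m = 1) already fit training data
  best; the sweep favors m > 1 exactly when queries are sparse — the
  regime real tract-level query data occupy.
* **Metrics** are computed on predictions pooled across folds (per-fold
  values are reported alongside); correlation is Pearson by default with
  Spearman behind a flag.
* **Cross-validation folds** are uniform random over tracts, not spatially
  blocked; spatially blocked CV would be a natural extension.
* **Determinism**: every stochastic step (generators, embedding training,
  fold assignment, forest growth) is seeded; forests run single-threaded.
  Writers emit 17-significant-digit decimals so a written-and-reloaded
  experiment reproduces the in-memory one exactly.
* **Interchange formats** are all plain text: GeoJSON (planar km
  coordinates) for tracts, CSV for tabular data, JSON-lines for the query
  log, and an ESRI ASCII grid with a JSON legend sidecar for the raster.

## The embedding

No skip-gram implementation exists in this package's R dependency set, and
the ranking it feeds is central to the method, so the package implements
skip-gram with negative sampling in C++ (via Rcpp): dynamic window
shrinkage, five negative samples drawn from the unigram distribution raised
to the 3/4 power, linear learning-rate decay, tabulated sigmoid, and a
self-contained linear-congruential RNG so training is bit-reproducible for
a given seed. Category labels for ranked terms are an explicit input
(`relevance_labels`) rather than a guess: in the synthetic setting they come
from the generator's known vocabulary, in real use from human curation.

## Problem sizes used in the checks

The test suite exercises oracle equivalence on randomized instances of up to
200 tracts and 50×50 rasters across 20 seeds; parameter recovery and null
calibration on the 500-tract reference city (five model re-seeds on the same
data for stability); keyword recovery on a 2,000-query planted-synonym
corpus (five training seeds) plus a 60-tract end-to-end city; and importance
sanity over 20 replicates of a single-informative-feature design at
n = 200. These sizes were chosen as the smallest at which the distributional
claims are stable.

## Known limitations

* The synthetic query signal is generated directly from prevalence; real
  query volume reflects awareness, access and media effects that can
  decouple searching from suffering.
* Census proportions are symmetric-Dirichlet and mutually independent given
  the block structure — real demographics are strongly correlated across
  blocks (age with race, poverty with both).
* The linear-with-offsets prevalence model is a convenient stand-in; the
  estimator itself is nonparametric and makes no use of that form.
* Importances are impurity-based, inheriting the known bias toward
  high-cardinality features; permutation importance is not implemented.
* No uncertainty intervals accompany predictions.
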