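Package: tractprev
Title: Census-Tract Disease Prevalence Estimation from Search-Query Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-area estimation of chronic respiratory illness prevalence
    (asthma, COPD) at census-tract resolution from search-query-derived
    features, optionally combined with land-cover and census demographic
    features. Provides a synthetic-city generator (tract tiling, demographics,
    categorical land-cover raster, ground-truth prevalence, geo-located query
    log), skip-gram keyword expansion from seed illness terms, per-tract
    normalized query counts with m-nearest-tract smoothing, land-cover
    proportion and pixel-adjacency features, and a seeded random-forest
    estimator evaluated by k-fold cross-validation with Pearson correlation,
    mean absolute error, and node-purity feature importances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
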