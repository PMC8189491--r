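#' Simulate a complete synthetic city
#'
#' One-call wrapper chaining the five generators under sub-seeds derived from
#' a single master seed: tract tiling, demographics, land cover, ground-truth
#' prevalence, and the geo-located query log. The defaults are the package's
#' reference study conditions (500 tracts, 4 states, 5% of residents issuing
#' on average 20 queries each, signal strength 2, prevalence noise 1
#' percentage point around bases 9.783% / 6.416%).
#'
#' @param n_tracts number of tracts.
#' @param seed master seed; the generators use `seed`, `seed + 1e4`,
#'   `seed + 2e4`, ... so stages stay independently reproducible.
#' @param vocab disease `keyword_set` for the query generator.
#' @param users_per_capita,queries_per_user,signal_strength,noise_sd
#'   forwarded to the generators.
#' @param ... further arguments forwarded to [generate_queries()].
#' @return a `synthetic_city`: list with `tracts`, `census`, `landcover`,
#'   `prevalence`, `queries`, `vocab`, `seed`.
#' @export
simulate_city <- function(n_tracts = 500, seed = 1, vocab = default_keywords(),
                          users_per_capita = 0.05, queries_per_user = 20,
                          signal_strength = 2, noise_sd = 1, ...) {
  tracts <- generate_tracts(n_tracts, seed = seed)
  census <- generate_census(tracts, seed = seed + 10000L)
  landcover <- generate_landcover(tracts, seed = seed + 20000L)
  prevalence <- generate_prevalence(tracts, census, landcover,
                                    noise_sd = noise_sd,
                                    seed = seed + 30000L)
  queries <- generate_queries(tracts, prevalence, vocab = vocab,
                              users_per_capita = users_per_capita,
                              queries_per_user = queries_per_user,
                              signal_strength = signal_strength,
                              seed = seed + 40000L, ...)
  structure(list(tracts = tracts, census = census, landcover = landcover,
                 prevalence = prevalence, queries = queries, vocab = vocab,
                 seed = seed),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf("<synthetic_city> seed %d\n", x$seed))
  print(x$tracts); print(x$queries)
  invisible(x)
}

#' Filter tracts by data completeness and the privacy threshold
#'
#' Retains tracts with a complete census row, at least one attributed
#' land-cover cell, and at least `threshold` distinct users in the query log.
#' Excluded tracts are recorded with their first matching reason, checked in
#' the order `missing_census`, `missing_landcover`,
#' `under_privacy_threshold` (data-completeness reasons before privacy).
#'
#' @param tracts a `tract_set`.
#' @param log a `query_log`.
#' @param census a `census_table`.
#' @param raster a `landcover_raster`.
#' @param threshold minimum distinct users per tract (default 50).
#' @return list with `retained` (a `tract_set`) and `ledger` (data.frame
#'   `tract_id`, `reason` for every excluded tract).
#' @export
filter_tracts <- function(tracts, log, census, raster, threshold = 50) {
  stopifnot(inherits(tracts, "tract_set"))
  if (threshold < 1) stop_invalid("`threshold` must be >= 1")
  ids <- tracts$tracts$tract_id
  cens_ids <- as.data.frame(census)$tract_id
  cens_ok <- ids %in% cens_ids[stats::complete.cases(as.data.frame(census))]
  assign <- raster_tract_assignment(raster, tracts)
  lc_ok <- ids %in% unique(assign[!is.na(assign)])
  act <- tract_activity(log)
  users <- act$n_users[match(ids, act$tract_id)]
  users[is.na(users)] <- 0L
  priv_ok <- users >= threshold

  reason <- rep(NA_character_, length(ids))
  reason[!cens_ok] <- "missing_census"
  reason[is.na(reason) & !lc_ok] <- "missing_landcover"
  reason[is.na(reason) & !priv_ok] <- "under_privacy_threshold"

  ledger <- data.frame(tract_id = ids[!is.na(reason)],
                       reason = reason[!is.na(reason)],
                       stringsAsFactors = FALSE)
  retained <- subset_tracts(tracts, ids[is.na(reason)])
  list(retained = retained, ledger = ledger)
}

#' Build the per-variant feature tables of a synthetic city
#'
#' Computes normalized keyword counts plus category sums and land-cover
#' proportion/adjacency features, smooths both with the shared
#' `m`-nearest-neighbor index, and returns the four model variants:
#' `search` (smoothed query features), `search_state` (+ state),
#' `search_land` (+ smoothed land-cover), and `search_land_census`
#' (+ census and state). Census features are never smoothed.
#'
#' @param tracts the retained `tract_set`.
#' @param log a `query_log`.
#' @param census a `census_table`.
#' @param raster a `landcover_raster`.
#' @param keywords a `keyword_set`.
#' @param m neighbor-smoothing window (default 8).
#' @return named list of `feature_table`s, one per variant.
#' @export
build_variant_features <- function(tracts, log, census, raster, keywords,
                                   m = 8) {
  idx <- nearest_neighbors(tracts, m)
  log <- subset_query_log(log, tracts$tracts$tract_id)
  q <- category_sums(normalized_counts(log, keywords, tracts), keywords)
  q_sm <- neighbor_smooth(q, idx)
  lc <- merge_features(list(landcover_proportions(raster, tracts),
                            adjacency_features(raster, tracts)))
  lc_sm <- neighbor_smooth(lc, idx)
  cens <- census_features(census, tracts)
  list(
    search = q_sm,
    search_state = merge_features(list(q_sm), state_feature = TRUE,
                                  tracts = tracts),
    search_land = merge_features(list(q_sm, lc_sm)),
    search_land_census = merge_features(list(q_sm, lc_sm, cens),
                                        state_feature = TRUE, tracts = tracts)
  )
}

#' Sweep the neighbor-smoothing window m
#'
#' For each `m`, smooths the query features with the shared neighbor index,
#' fits the forest on all retained tracts and records the training-data
#' correlation per outcome (the sweep diagnoses how much spatial averaging
#' the sparse per-tract counts need; it deliberately uses training-set fit,
#' not cross-validation, and is labelled as such).
#'
#' @param city a `synthetic_city` (or list with the same elements).
#' @param m_values windows to sweep (default `c(1, 4, 8, 16, 32)`).
#' @param outcomes outcome names (default the prevalence columns).
#' @param config a [model_config()].
#' @param threshold privacy threshold forwarded to [filter_tracts()].
#' @return data.frame (`m`, `outcome`, `correlation_training`) with
#'   `attr(, "best_m")`, the argmax per outcome.
#' @export
sweep_m <- function(city, m_values = c(1, 4, 8, 16, 32),
                    outcomes = NULL, config = model_config(),
                    threshold = 50) {
  flt <- filter_tracts(city$tracts, city$queries, city$census,
                       city$landcover, threshold)
  tr <- flt$retained
  if (nrow(tr$tracts) == 0L) stop_invalid("no tracts retained")
  if (any(m_values < 1) || any(m_values > nrow(tr$tracts))) {
    stop_invalid("`m_values` must lie in [1, %d]", nrow(tr$tracts))
  }
  outcomes <- outcomes %||% setdiff(names(as.data.frame(city$prevalence)),
                                    "tract_id")
  log <- subset_query_log(city$queries, tr$tracts$tract_id)
  q <- category_sums(normalized_counts(log, city$vocab, tr), city$vocab)
  rows <- list()
  for (m in m_values) {
    q_sm <- neighbor_smooth(q, nearest_neighbors(tr, m))
    for (oc in outcomes) {
      fit <- fit_forest(q_sm, city$prevalence, oc, config)
      pred <- predict(fit, q_sm)
      actual <- as.data.frame(city$prevalence)[[oc]][
        match(q_sm$tract_id, city$prevalence$tract_id)]
      rows[[length(rows) + 1L]] <- data.frame(
        m = m, outcome = oc,
        correlation_training = pearson_correlation(pred, actual))
    }
  }
  out <- do.call(rbind, rows)
  best <- vapply(outcomes, function(oc) {
    sub <- out[out$outcome == oc, ]
    sub$m[which.max(sub$correlation_training)]
  }, numeric(1))
  structure(out, best_m = best)
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the data (a
#' `synthetic_city`, or paths to files written by the package's writers),
#' the variants to run, the smoothing window, privacy threshold and model
#' settings.
#'
#' @param city a `synthetic_city`, or `NULL` if `paths` are given.
#' @param paths named list of input files (`tracts`, `census`, `landcover`,
#'   `prevalence`, `queries`, `keywords`) as written by the package writers.
#' @param variants subset of `search`, `search_state`, `search_land`,
#'   `search_land_census`.
#' @param outcomes outcome names; default the prevalence columns.
#' @param m smoothing window (default 8).
#' @param m_values sweep grid (default `c(1, 4, 8, 16, 32)`).
#' @param threshold privacy threshold (default 50 distinct users).
#' @param model a [model_config()].
#' @param run_sweep include the m-sweep in the report?
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(city = NULL, paths = NULL,
                              variants = c("search", "search_state",
                                           "search_land",
                                           "search_land_census"),
                              outcomes = NULL, m = 8,
                              m_values = c(1, 4, 8, 16, 32),
                              threshold = 50, model = model_config(),
                              run_sweep = FALSE) {
  allowed <- c("search", "search_state", "search_land", "search_land_census")
  bad <- setdiff(variants, allowed)
  if (length(bad)) stop_invalid("unknown variant(s): %s", paste(bad, collapse = ", "))
  if (is.null(city) && is.null(paths)) {
    stop_invalid("either `city` or `paths` must be given")
  }
  structure(list(city = city, paths = paths, variants = variants,
                 outcomes = outcomes, m = m, m_values = m_values,
                 threshold = threshold, model = model,
                 run_sweep = isTRUE(run_sweep)),
            class = "experiment_config")
}

load_city_from_paths <- function(paths) {
  need <- c("tracts", "census", "landcover", "prevalence", "queries",
            "keywords")
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    stop_invalid("`paths` missing entries: %s", paste(missing, collapse = ", "))
  }
  for (p in unlist(paths[need])) {
    if (!file.exists(p)) stop_invalid("input file not readable: %s", p)
  }
  structure(list(
    tracts = read_tracts_geojson(paths$tracts),
    census = read_tract_table(paths$census, "census_table"),
    landcover = read_landcover_asc(paths$landcover),
    prevalence = read_tract_table(paths$prevalence, "prevalence_table"),
    queries = read_query_log(paths$queries,
                             if (grepl("\\.csv$", paths$queries)) "csv" else "jsonl"),
    vocab = read_keywords(paths$keywords),
    seed = NA_integer_
  ), class = "synthetic_city")
}

#' Run the end-to-end estimation experiment
#'
#' Filters tracts, builds the per-variant feature tables at the configured
#' `m`, cross-validates every requested variant for every outcome, and
#' (optionally) runs the m-sweep. If `out_dir` is given, persists the report
#' as JSON plus CSV tables (per-tract out-of-fold predictions, importances,
#' the exclusion ledger) — all content-deterministic for fixed config and
#' seeds.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory (created if needed).
#' @return an `experiment_report`: list with `metrics` (variant x outcome
#'   data.frame of correlation and MAE), `cv` (nested cv_result objects),
#'   `sweep`, `exclusions`, `n_retained`, `config_summary`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  city <- config$city %||% load_city_from_paths(config$paths)
  flt <- filter_tracts(city$tracts, city$queries, city$census,
                       city$landcover, config$threshold)
  tr <- flt$retained
  if (nrow(tr$tracts) == 0L) {
    stop_invalid("empty result: no tracts survive filtering")
  }
  outcomes <- config$outcomes %||%
    setdiff(names(as.data.frame(city$prevalence)), "tract_id")
  feats <- build_variant_features(tr, city$queries, city$census,
                                  city$landcover, city$vocab, m = config$m)
  cv <- list()
  rows <- list()
  for (variant in config$variants) {
    for (oc in outcomes) {
      res <- cross_validate(feats[[variant]], city$prevalence, oc,
                            config$model)
      cv[[variant]][[oc]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant, outcome = oc,
        correlation = res$correlation, mae = res$mae,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  sweep <- if (config$run_sweep) {
    sweep_m(city, config$m_values, outcomes, config$model, config$threshold)
  }
  report <- structure(
    list(metrics = metrics, cv = cv, sweep = sweep,
         exclusions = flt$ledger, n_retained = nrow(tr$tracts),
         config_summary = list(m = config$m, threshold = config$threshold,
                               variants = config$variants,
                               outcomes = outcomes,
                               n_trees = config$model$n_trees,
                               seed = config$model$seed)),
    class = "experiment_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d tracts retained, %d excluded\n",
              x$n_retained, nrow(x$exclusions)))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Persist an experiment report to a directory
#'
#' Writes `metrics.json` (metrics, config summary, exclusion counts),
#' `predictions_<variant>_<outcome>.csv`, `importances_<variant>_<outcome>.csv`,
#' `exclusions.csv` and, when present, `m_sweep.csv`. Files contain no
#' timestamps, so identical runs are byte-identical.
#'
#' @param report an `experiment_report`.
#' @param out_dir output directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  excl_counts <- as.list(table(report$exclusions$reason))
  jsonlite::write_json(
    list(metrics = report$metrics, n_retained = report$n_retained,
         exclusion_counts = excl_counts,
         config = report$config_summary),
    file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (variant in names(report$cv)) {
    for (oc in names(report$cv[[variant]])) {
      res <- report$cv[[variant]][[oc]]
      write.csv(res$predictions,
                file.path(out_dir, sprintf("predictions_%s_%s.csv", variant, oc)),
                row.names = FALSE, quote = FALSE)
      write.csv(res$importances,
                file.path(out_dir, sprintf("importances_%s_%s.csv", variant, oc)),
                row.names = FALSE, quote = FALSE)
    }
  }
  write.csv(report$exclusions, file.path(out_dir, "exclusions.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(report$sweep)) {
    write.csv(as.data.frame(report$sweep), file.path(out_dir, "m_sweep.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

#' Write all synthetic-city inputs to a directory
#'
#' Persists every generated artifact in its interchange format: tracts as
#' GeoJSON, census and prevalence as CSV, land cover as an ESRI ASCII grid,
#' the query log as JSON-lines, and the keyword vocabulary as CSV.
#'
#' @param city a `synthetic_city`.
#' @param out_dir output directory.
#' @return named list of the written paths.
#' @export
write_city <- function(city, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    tracts = file.path(out_dir, "tracts.geojson"),
    census = file.path(out_dir, "census.csv"),
    landcover = file.path(out_dir, "landcover.asc"),
    prevalence = file.path(out_dir, "prevalence.csv"),
    queries = file.path(out_dir, "queries.jsonl"),
    keywords = file.path(out_dir, "keywords.csv")
  )
  write_tracts_geojson(city$tracts, paths$tracts)
  write_tract_table(city$census, paths$census)
  write_landcover_asc(city$landcover, paths$landcover)
  write_tract_table(city$prevalence, paths$prevalence)
  write_query_log(city$queries, paths$queries, "jsonl")
  write_keywords(city$vocab, paths$keywords)
  invisible(paths)
}
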