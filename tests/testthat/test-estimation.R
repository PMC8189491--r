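# shared small regression scenario
make_xy <- function(n, p_noise = 5, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("T%04d", seq_len(n))
    signal <- runif(n)
    df <- data.frame(tract_id = ids, signal = signal)
    for (j in seq_len(p_noise)) df[[sprintf("noise%02d", j)]] <- runif(n)
    targets <- data.frame(tract_id = ids)
    targets$asthma <- 5 + 10 * signal
    list(features = feature_table(df, "query"), targets = targets)
  })
}

test_that("the forest memorises a deterministic single-feature target", {
  d <- make_xy(120, seed = 1)
  fit <- fit_forest(d$features, d$targets, "asthma",
                    model_config(n_trees = 200, seed = 1))
  pred <- predict(fit, d$features)
  expect_gt(pearson_correlation(pred, d$targets$asthma), 0.99)
})

test_that("permuted targets carry no out-of-fold signal", {
  d <- make_xy(500, seed = 2)
  perm <- d$targets
  perm$asthma <- withr::with_seed(3, sample(perm$asthma))
  cv <- cross_validate(d$features, perm, "asthma",
                       model_config(n_trees = 200, seed = 1))
  expect_lt(abs(cv$correlation), 0.15)
})

test_that("fitting and prediction are deterministic given the seed", {
  d <- make_xy(100, seed = 4)
  f1 <- fit_forest(d$features, d$targets, "asthma",
                   model_config(n_trees = 100, seed = 9))
  f2 <- fit_forest(d$features, d$targets, "asthma",
                   model_config(n_trees = 100, seed = 9))
  expect_identical(predict(f1, d$features), predict(f2, d$features))
  cv1 <- cross_validate(d$features, d$targets, "asthma",
                        model_config(n_trees = 100, seed = 9))
  cv2 <- cross_validate(d$features, d$targets, "asthma",
                        model_config(n_trees = 100, seed = 9))
  expect_identical(cv1$predictions, cv2$predictions)
})

test_that("misaligned or incomplete inputs are rejected", {
  d <- make_xy(30, seed = 5)
  short <- d$targets[-1, ]
  expect_error(fit_forest(d$features, short, "asthma"), "missing")
  expect_error(fit_forest(d$features, d$targets, "copd"), "outcome")
  holey <- d$features
  holey$signal[3] <- NA
  expect_error(fit_forest(holey, d$targets, "asthma"), "missing cells")
})

test_that("cross-validation partitions tracts into balanced folds", {
  d <- make_xy(103, seed = 6)
  cv <- cross_validate(d$features, d$targets, "asthma",
                       model_config(n_trees = 50, seed = 2))
  sizes <- table(cv$predictions$fold)
  expect_length(sizes, 5L)
  expect_lte(diff(range(sizes)), 1)
  # every tract predicted exactly once out of fold
  expect_setequal(cv$predictions$tract_id, d$features$tract_id)
  expect_false(anyDuplicated(cv$predictions$tract_id) > 0)
  expect_false(anyNA(cv$predictions$predicted))
  expect_error(cross_validate(d$features[1:4, ], d$targets, "asthma"),
               "folds|rows")
})

test_that("pooled metrics match metrics recomputed from the predictions", {
  d <- make_xy(80, seed = 7)
  cv <- cross_validate(d$features, d$targets, "asthma",
                       model_config(n_trees = 50, seed = 3))
  expect_equal(cv$correlation,
               pearson_correlation(cv$predictions$predicted,
                                   cv$predictions$actual))
  expect_equal(cv$mae,
               mean_absolute_error(cv$predictions$predicted,
                                   cv$predictions$actual))
  # round-trip through the persisted CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(cv$predictions, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(pearson_correlation(back$predicted, back$actual),
               cv$correlation, tolerance = 1e-12)
  expect_equal(mean_absolute_error(back$predicted, back$actual),
               cv$mae, tolerance = 1e-12)
})

test_that("correlation metric matches closed forms and guards degeneracy", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 3)), 1.0)
  x <- c(1, 2, 3)
  expect_equal(pearson_correlation(x, -x + 4), -1.0)
  # hand computation: Sxy = 5, Sxx = 2, Syy = 38/3
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 7)),
               5 / sqrt(2 * 38 / 3), tolerance = 1e-9)
  expect_equal(round(pearson_correlation(c(1, 2, 3), c(2, 4, 7)), 5), 0.9934)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation(1:3, 1:4), "length")
})

test_that("MAE matches hand computations and is shift-invariant", {
  expect_equal(mean_absolute_error(c(3, 4), c(3, 4)), 0)
  expect_equal(mean_absolute_error(c(1, 2), c(2, 4)), 1.5)
  a <- runif(10); b <- runif(10)
  expect_equal(mean_absolute_error(a, b), mean_absolute_error(a + 7, b + 7))
  expect_error(mean_absolute_error(1:3, 1:4), "length")
})

test_that("the informative feature dominates node-purity importances", {
  wins <- 0L
  for (rep in 1:20) {
    d <- make_xy(200, p_noise = 9, seed = 100 + rep)
    fit <- fit_forest(d$features, d$targets, "asthma",
                      model_config(n_trees = 200, seed = rep))
    imp <- feature_importance(fit)
    if (imp$feature[1] == "signal") wins <- wins + 1L
  }
  expect_gte(wins, 19L)  # >= 95% of replicates
})

test_that("pure-noise targets yield flat importances", {
  withr::with_seed(11, {
    ids <- sprintf("T%04d", 1:300)
    df <- data.frame(tract_id = ids)
    for (j in 1:10) df[[sprintf("n%02d", j)]] <- runif(300)
    targets <- data.frame(tract_id = ids, asthma = rnorm(300))
  })
  fit <- fit_forest(feature_table(df, "query"), targets, "asthma",
                    model_config(n_trees = 300, seed = 1))
  imp <- feature_importance(fit)
  expect_true(all(imp$importance >= 0))
  expect_lt(max(imp$importance), 3 * median(imp$importance))
})

test_that("importance output is sorted, complete, and size-limited", {
  d <- make_xy(50, seed = 12)
  fit <- fit_forest(d$features, d$targets, "asthma",
                    model_config(n_trees = 50, seed = 1))
  imp <- feature_importance(fit)
  expect_setequal(imp$feature, setdiff(names(d$features), "tract_id"))
  expect_true(all(diff(imp$importance) <= 1e-12))
  expect_equal(nrow(feature_importance(fit, top_n = 5)), 5L)
  expect_error(feature_importance(lm(y ~ x, data.frame(x = 1:5, y = 1:5))),
               "prevalence_forest")
})

test_that("spearman correlation flavour is available", {
  d <- make_xy(60, seed = 13)
  cv_s <- cross_validate(d$features, d$targets, "asthma",
                         model_config(n_trees = 50, seed = 1),
                         method = "spearman")
  expect_true(is.finite(cv_s$correlation))
  expect_equal(cv_s$method, "spearman")
})

test_that("out-of-fold prediction ignores the tract's own target", {
  # poison one tract's target: its out-of-fold prediction must not chase it,
  # because the fold holding it out never sees that value in training
  d <- make_xy(100, seed = 14)
  poisoned <- d$targets
  victim <- poisoned$tract_id[1]
  poisoned$asthma[1] <- 1000
  cv <- cross_validate(d$features, poisoned, "asthma",
                       model_config(n_trees = 100, seed = 5))
  pred_victim <- cv$predictions$predicted[cv$predictions$tract_id == victim]
  expect_lt(pred_victim, 500)  # far from the poisoned value
})
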