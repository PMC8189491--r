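#' Random-forest model configuration
#'
#' Hyperparameters of the prevalence regressor. Defaults follow the usual
#' regression-forest conventions: 500 trees, `ceiling(p / 3)` candidate
#' features per split, minimum node size 5, 5-fold cross-validation.
#'
#' @param n_trees number of trees (>= 1).
#' @param mtry features tried per split; `NULL` = `ceiling(p / 3)`.
#' @param min_leaf minimum node size.
#' @param seed integer seed controlling forest growth and fold assignment.
#' @param k_folds number of CV folds (>= 2).
#' @return a `model_config` list.
#' @export
model_config <- function(n_trees = 500, mtry = NULL, min_leaf = 5,
                         seed = 1, k_folds = 5) {
  if (n_trees < 1) stop_invalid("`n_trees` must be >= 1")
  if (k_folds < 2) stop_invalid("`k_folds` must be >= 2")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed),
                 k_folds = as.integer(k_folds)),
            class = "model_config")
}

align_xy <- function(features, targets, outcome) {
  stopifnot(inherits(features, "feature_table"))
  tg <- as.data.frame(targets)
  if (!outcome %in% names(tg)) {
    stop_invalid("outcome `%s` not found in targets", outcome)
  }
  y <- tg[[outcome]][match(features$tract_id, tg$tract_id)]
  if (anyNA(y)) stop_invalid("targets missing for some feature rows")
  x <- as.data.frame(features)[, feature_names(features), drop = FALSE]
  if (anyNA(x)) stop_invalid("feature table has missing cells")
  list(x = x, y = y, ids = features$tract_id)
}

#' Fit the random-forest prevalence model
#'
#' Regression forest of tract prevalence on the feature table, grown with a
#' fixed seed on a single thread so repeated fits are identical. Importances
#' are impurity-based (node purity: total variance decrease from splits on
#' the feature).
#'
#' @param features a `feature_table`.
#' @param targets a `prevalence_table` (or data.frame with `tract_id` and an
#'   `outcome` column, in percent).
#' @param outcome outcome column name, e.g. `"asthma"`.
#' @param config a [model_config()].
#' @return a `prevalence_forest` handle supporting [predict()] and
#'   [feature_importance()].
#' @export
fit_forest <- function(features, targets, outcome, config = model_config()) {
  xy <- align_xy(features, targets, outcome)
  p <- ncol(xy$x)
  fit <- ranger::ranger(
    x = xy$x, y = xy$y,
    num.trees = config$n_trees,
    mtry = config$mtry %||% ceiling(p / 3),
    min.node.size = config$min_leaf,
    importance = "impurity",
    seed = config$seed,
    num.threads = 1
  )
  structure(list(fit = fit, feature_names = colnames(xy$x),
                 outcome = outcome, config = config),
            class = "prevalence_forest")
}

#' @export
print.prevalence_forest <- function(x, ...) {
  cat(sprintf("<prevalence_forest> outcome %s, %d trees on %d features\n",
              x$outcome, x$config$n_trees, length(x$feature_names)))
  invisible(x)
}

#' Predict tract prevalence from a fitted forest
#' @param object a `prevalence_forest`.
#' @param features a `feature_table` with the training columns.
#' @param ... ignored.
#' @return numeric vector of predicted prevalence (percent), one per row.
#' @export
predict.prevalence_forest <- function(object, features, ...) {
  x <- as.data.frame(features)[, object$feature_names, drop = FALSE]
  ranger::predictions(predict(object$fit, data = x, num.threads = 1))
}

#' Node-purity feature importances
#'
#' Impurity importance (summed variance decrease over all splits on the
#' feature), sorted descending with lexicographic tie-breaks.
#'
#' @param model a `prevalence_forest`.
#' @param top_n optional number of top features to return.
#' @return data.frame with `rank`, `feature`, `importance` (>= 0).
#' @export
feature_importance <- function(model, top_n = NULL) {
  if (!inherits(model, "prevalence_forest")) {
    stop_invalid("`model` must be a fitted prevalence_forest")
  }
  imp <- ranger::importance(model$fit)
  ord <- order(-imp, names(imp))
  out <- data.frame(rank = seq_along(ord), feature = names(imp)[ord],
                    importance = unname(imp[ord]), stringsAsFactors = FALSE)
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Pearson correlation of predictions and ground truth
#'
#' @param pred,actual equal-length numeric vectors (length >= 2, both with
#'   nonzero variance).
#' @return correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(pred, actual) {
  if (length(pred) != length(actual)) stop_invalid("length mismatch")
  if (length(pred) < 2L) stop_invalid("need at least two observations")
  if (sd(pred) == 0 || sd(actual) == 0) {
    stop_invalid("correlation undefined: zero variance")
  }
  cor(pred, actual)
}

#' Mean absolute error in percentage points
#'
#' @param pred,actual equal-length numeric vectors on the percent scale.
#' @return mean of `|pred - actual|` (>= 0).
#' @export
mean_absolute_error <- function(pred, actual) {
  if (length(pred) != length(actual)) stop_invalid("length mismatch")
  mean(abs(pred - actual))
}

#' k-fold cross-validated evaluation of the prevalence model
#'
#' Randomly partitions tracts into `k_folds` balanced folds (seeded with
#' `config$seed`), trains on each complement and predicts the held-out fold,
#' then scores the pooled out-of-fold predictions by correlation and MAE.
#' Per-fold metrics are reported alongside. Importances come from a forest
#' refit on all rows with the same configuration.
#'
#' @inheritParams fit_forest
#' @param method correlation flavor, `"pearson"` (default) or `"spearman"`.
#' @return a `cv_result`: list with `predictions` (tract_id, fold, actual,
#'   predicted), `correlation`, `mae`, `per_fold`, `importances`, `outcome`,
#'   `method`.
#' @export
cross_validate <- function(features, targets, outcome,
                           config = model_config(),
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xy <- align_xy(features, targets, outcome)
  n <- length(xy$y)
  k <- config$k_folds
  if (n < k) stop_invalid("fewer rows (%d) than folds (%d)", n, k)
  folds <- with_seed(config$seed, sample(rep(seq_len(k), length.out = n)))
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- folds == f
    sub <- feature_table(
      data.frame(tract_id = xy$ids[!test], xy$x[!test, , drop = FALSE],
                 check.names = FALSE, stringsAsFactors = FALSE),
      provenance = attr(features, "provenance") %||% "query",
      m = attr(features, "m") %||% 1L)
    tg <- data.frame(tract_id = xy$ids[!test], stringsAsFactors = FALSE)
    tg[[outcome]] <- xy$y[!test]
    fit <- fit_forest(sub, tg, outcome, config)
    x_test <- data.frame(xy$x[test, , drop = FALSE], check.names = FALSE)
    pred[test] <- ranger::predictions(
      predict(fit$fit, data = x_test, num.threads = 1))
  }
  corr <- if (method == "pearson") {
    pearson_correlation(pred, xy$y)
  } else {
    cor(pred, xy$y, method = "spearman")
  }
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    sel <- folds == f
    data.frame(fold = f, n = sum(sel),
               correlation = cor(pred[sel], xy$y[sel], method = method),
               mae = mean_absolute_error(pred[sel], xy$y[sel]))
  }))
  full_fit <- fit_forest(features, targets, outcome, config)
  structure(
    list(predictions = data.frame(tract_id = xy$ids, fold = folds,
                                  actual = xy$y, predicted = pred,
                                  stringsAsFactors = FALSE),
         correlation = corr,
         mae = mean_absolute_error(pred, xy$y),
         per_fold = per_fold,
         importances = feature_importance(full_fit),
         outcome = outcome, method = method),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: r = %.3f, MAE = %.3f (%d tracts, %d folds)\n",
              x$outcome, x$correlation, x$mae, nrow(x$predictions),
              nrow(x$per_fold)))
  invisible(x)
}
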