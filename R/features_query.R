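#' Per-tract normalized keyword counts
#'
#' For every keyword `k` and tract `i`, computes the fraction of tract `i`'s
#' queries whose token set contains `k`:
#' `S_i(k) = |queries in i containing k| / |queries in i|`.
#' Matching is exact token membership (not substring), and a query counts at
#' most once per keyword however often the token repeats. Tracts without any
#' queries get 0 for every keyword and are listed in
#' `attr(, "zero_event_tracts")`.
#'
#' @param log a `query_log`; every event's tract must be in `tracts`.
#' @param keywords a `keyword_set`.
#' @param tracts a `tract_set` defining the rows of the output.
#' @return a `feature_table` with one column per keyword, provenance
#'   `query`, values in `[0, 1]`.
#' @export
normalized_counts <- function(log, keywords, tracts) {
  stopifnot(inherits(log, "query_log"), inherits(keywords, "keyword_set"),
            inherits(tracts, "tract_set"))
  ids <- tracts$tracts$tract_id
  bad <- setdiff(unique(log$events$tract_id), ids)
  if (length(bad)) {
    stop_invalid("query log references unknown tract(s): %s",
                 paste(head(bad, 5), collapse = ", "))
  }
  ev <- log$events
  totals <- ev[, list(n = .N), by = "tract_id"]

  hits <- log$tokens[log$tokens$token %in% keywords$keyword]
  hits <- unique(hits, by = c("event_id", "token"))
  hits <- merge(hits, ev[, c("event_id", "tract_id")], by = "event_id")
  counts <- hits[, list(cnt = .N), by = c("tract_id", "token")]

  mat <- matrix(0, nrow = length(ids), ncol = nrow(keywords),
                dimnames = list(ids, keywords$keyword))
  if (nrow(counts)) {
    mat[cbind(match(counts$tract_id, ids),
              match(counts$token, keywords$keyword))] <- counts$cnt
  }
  denom <- totals$n[match(ids, totals$tract_id)]
  zero <- ids[is.na(denom) | denom == 0]
  denom[is.na(denom) | denom == 0] <- 1  # rows forced to 0 below anyway
  mat <- mat / denom
  mat[ids %in% zero, ] <- 0

  out <- data.frame(tract_id = ids, mat, stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = NULL)
  ft <- feature_table(out, provenance = "query")
  attr(ft, "zero_event_tracts") <- zero
  ft
}

#' Add per-category sum features
#'
#' Appends `sum_symptoms`, `sum_diseases` and `sum_medications`: row-wise
#' sums of the member keyword columns of each category (a sparsity remedy —
#' individual keyword rates are noisy, their category totals less so). An
#' empty category yields a zero column. Original columns are retained.
#'
#' @param table a `feature_table` of normalized counts covering `keywords`.
#' @param keywords the `keyword_set` defining category membership.
#' @return the input `feature_table` with three extra `query` columns.
#' @export
category_sums <- function(table, keywords) {
  stopifnot(inherits(table, "feature_table"), inherits(keywords, "keyword_set"))
  missing <- setdiff(keywords$keyword, feature_names(table))
  if (length(missing)) {
    stop_invalid("table lacks keyword column(s): %s",
                 paste(head(missing, 5), collapse = ", "))
  }
  sums <- c(sum_symptoms = "symptom", sum_diseases = "disease",
            sum_medications = "medication")
  df <- as.data.frame(table)
  for (nm in names(sums)) {
    cols <- keywords$keyword[keywords$category == sums[[nm]]]
    df[[nm]] <- if (length(cols)) {
      rowSums(df[, cols, drop = FALSE])
    } else {
      rep(0, nrow(df))
    }
  }
  prov <- attr(table, "provenance")
  prov[names(sums)] <- "query"
  feature_table(df, prov, m = attr(table, "m") %||% 1L)
}
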