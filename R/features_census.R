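#' Census proportions as model features
#'
#' Passes the 20 demographic proportions through as feature columns,
#' re-validating the block-sum invariants. Census features are never
#' neighbor-smoothed: demographics are defined strictly within tract
#' boundaries, unlike query or land-cover signals.
#'
#' @param census a `census_table`.
#' @param tracts optional `tract_set`; if given, every tract must have a
#'   census row (missing tracts raise an error listing their ids).
#' @return a `feature_table` with 20 columns, provenance `census`.
#' @export
census_features <- function(census, tracts = NULL) {
  validate_census(census)
  df <- as.data.frame(census)
  if (!is.null(tracts)) {
    stopifnot(inherits(tracts, "tract_set"))
    missing <- setdiff(tracts$tracts$tract_id, df$tract_id)
    if (length(missing)) {
      stop_invalid("census data missing for tract(s): %s",
                   paste(missing, collapse = ", "))
    }
    df <- df[match(tracts$tracts$tract_id, df$tract_id), , drop = FALSE]
  }
  cols <- unlist(census_blocks(), use.names = FALSE)
  feature_table(df[, c("tract_id", cols)], provenance = "census")
}

#' Merge feature tables and optionally add the state feature
#'
#' Column-binds feature tables sharing one tract set, optionally appending
#' the tract's state as a single integer-coded categorical column (tree
#' ensembles split on the codes directly; the code map is persisted in
#' `attr(, "state_codes")`).
#'
#' @param parts list of `feature_table`s over identical tract sets.
#' @param state_feature add the integer-coded `state` column?
#' @param tracts a `tract_set` (defines row order; required if
#'   `state_feature`).
#' @return a merged `feature_table`.
#' @export
merge_features <- function(parts, state_feature = FALSE, tracts = NULL) {
  if (!length(parts)) stop_invalid("`parts` must be a non-empty list")
  stopifnot(all(vapply(parts, inherits, logical(1), "feature_table")))
  ids <- parts[[1L]]$tract_id
  for (p in parts[-1L]) {
    if (!identical(sort(p$tract_id), sort(ids))) {
      stop_invalid("feature tables cover different tract sets")
    }
  }
  if (!is.null(tracts)) {
    if (!setequal(tracts$tracts$tract_id, ids)) {
      stop_invalid("feature tables do not match the tract set")
    }
    ids <- tracts$tracts$tract_id[tracts$tracts$tract_id %in% ids]
  }
  out <- data.frame(tract_id = ids, stringsAsFactors = FALSE)
  prov <- character(0)
  for (p in parts) {
    aligned <- as.data.frame(p)[match(ids, p$tract_id), , drop = FALSE]
    fn <- feature_names(p)
    dup <- intersect(fn, names(out))
    if (length(dup)) {
      stop_invalid("duplicate feature column(s): %s", paste(dup, collapse = ", "))
    }
    out[fn] <- aligned[fn]
    prov <- c(prov, attr(p, "provenance"))
  }
  state_codes <- NULL
  if (isTRUE(state_feature)) {
    if (is.null(tracts)) stop_invalid("`tracts` required for the state feature")
    states <- sort(unique(tracts$tracts$state_code))
    state_codes <- stats::setNames(seq_along(states), states)
    out$state <- unname(state_codes[
      tracts$tracts$state_code[match(ids, tracts$tracts$tract_id)]])
    prov <- c(prov, stats::setNames("state", "state"))
  }
  ms <- unique(vapply(parts, function(p) attr(p, "m") %||% 1L, integer(1)))
  ft <- feature_table(out, prov, m = if (length(ms) == 1L) ms else 1L)
  attr(ft, "state_codes") <- state_codes
  ft
}
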