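#' m-nearest-tract neighbor index
#'
#' For every tract, its `m` nearest tracts by Euclidean centroid distance —
#' itself (distance 0) plus the `m - 1` closest others. Distance ties are
#' broken by lexicographic tract id, making the index deterministic.
#'
#' @param tracts a `tract_set`.
#' @param m neighborhood size, `1 <= m <= n_tracts`.
#' @return a `neighbor_index` data.frame (`tract_id`, `rank`, `neighbor_id`,
#'   rank 1 = self) with `attr(, "m")`.
#' @export
nearest_neighbors <- function(tracts, m) {
  stopifnot(inherits(tracts, "tract_set"))
  n <- nrow(tracts$tracts)
  if (!is.numeric(m) || length(m) != 1L || m != round(m) || m < 1) {
    stop_invalid("`m` must be a positive integer")
  }
  if (m > n) stop_invalid("`m` (%d) exceeds the number of tracts (%d)", m, n)
  ids <- tracts$tracts$tract_id
  xy <- cbind(tracts$tracts$centroid_x, tracts$tracts$centroid_y)
  d <- as.matrix(stats::dist(xy))
  res <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], ids)[seq_len(m)]
    res[[i]] <- data.frame(tract_id = ids[i], rank = seq_len(m),
                           neighbor_id = ids[ord], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("neighbor_index", "data.frame"), m = as.integer(m))
}

#' Neighbor-average smoothing of a feature table
#'
#' Replaces every feature value by the unweighted mean of that column over
#' the tract's `m`-nearest-neighbor list (self included):
#' `Shat_i(k) = sum_{j in N_m(i)} S_j(k) / m`.
#' At `m = 1` this is the identity. Smoothing is a convex combination, so
#' `[0, 1]`-valued features stay in `[0, 1]`.
#'
#' @param table a `feature_table`.
#' @param index a `neighbor_index` covering every row of `table`.
#' @return a `feature_table` with the same shape; `attr(, "m")` records the
#'   window.
#' @export
neighbor_smooth <- function(table, index) {
  stopifnot(inherits(table, "feature_table"), inherits(index, "neighbor_index"))
  ids <- table$tract_id
  m <- attr(index, "m")
  missing <- setdiff(ids, unique(index$tract_id))
  if (length(missing)) {
    stop_invalid("neighbor index missing tract(s): %s",
                 paste(head(missing, 5), collapse = ", "))
  }
  idx <- index[index$tract_id %in% ids, , drop = FALSE]
  bad <- setdiff(idx$neighbor_id, ids)
  if (length(bad)) {
    stop_invalid("neighbor index refers to tract(s) absent from the table: %s",
                 paste(head(bad, 5), collapse = ", "))
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(match(idx$tract_id, ids), match(idx$neighbor_id, ids))] <- 1 / m
  x <- as.matrix(as.data.frame(table)[, feature_names(table), drop = FALSE])
  sm <- A %*% x
  out <- data.frame(tract_id = ids, sm, stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = NULL)
  feature_table(out, attr(table, "provenance"), m = m)
}
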