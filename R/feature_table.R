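#' Construct a feature table
#'
#' A tract-by-feature matrix stored as a data.frame with a `tract_id` key
#' column. Attributes record the provenance of every feature column
#' (`query`, `landcover`, `census` or `state`) and the neighbor-smoothing
#' window `m` applied (1 = raw).
#'
#' @param df data.frame with `tract_id` first and numeric feature columns.
#' @param provenance single string or named character vector per feature.
#' @param m smoothing window recorded on the table.
#' @return a `feature_table`.
#' @export
feature_table <- function(df, provenance, m = 1L) {
  if (!"tract_id" %in% names(df)) stop_invalid("`df` needs a tract_id column")
  feats <- setdiff(names(df), "tract_id")
  if (anyDuplicated(feats)) stop_invalid("duplicate feature columns")
  if (length(provenance) == 1L) {
    provenance <- stats::setNames(rep(provenance, length(feats)), feats)
  }
  if (!setequal(names(provenance), feats)) {
    stop_invalid("`provenance` must name every feature column")
  }
  df <- df[, c("tract_id", feats), drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("feature_table", "data.frame"),
            provenance = provenance[feats], m = as.integer(m))
}

feature_names <- function(x) setdiff(names(x), "tract_id")

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d tracts x %d features (m = %d)\n",
              nrow(x), length(feature_names(x)), attr(x, "m") %||% 1L))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) {
    tb <- table(prov)
    cat("  provenance:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Read / write a feature table as CSV
#' @param x a `feature_table`.
#' @param path file path.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  # 17 significant digits: parsing the file restores exact values
  write.csv(format_doubles_exact(as.data.frame(x)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param provenance provenance to re-attach on read.
#' @export
read_feature_table <- function(path, provenance = "query") {
  feature_table(read.csv(path, stringsAsFactors = FALSE), provenance)
}
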