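#' Train a skip-gram word embedding on a query corpus
#'
#' Skip-gram with negative sampling over single-query "sentences". Words with
#' similar search contexts end up with similar vectors, which is what the
#' downstream keyword ranking exploits. Defaults follow common practice for
#' search-query text: embedding dimension `d = 100` and context window
#' `w = 6` (a typical query length).
#'
#' @param corpus list of character vectors (one tokenised query each), or a
#'   `query_log`.
#' @param d embedding dimension (>= 2).
#' @param w context window (>= 1).
#' @param epochs training passes over the corpus.
#' @param min_count drop tokens occurring fewer than `min_count` times.
#' @param negative number of negative samples per positive pair.
#' @param alpha initial learning rate (decays linearly).
#' @param seed integer seed; training is single-threaded and deterministic.
#' @return a `skipgram_model`: list with `vectors` (vocab x d matrix, rownames
#'   are words), `counts`, and the training parameters.
#' @export
train_embedding <- function(corpus, d = 100, w = 6, epochs = 5,
                            min_count = 5, negative = 5, alpha = 0.025,
                            seed = 1) {
  if (inherits(corpus, "query_log")) corpus <- corpus_from_log(corpus)
  if (!is.list(corpus) || length(corpus) == 0L) {
    stop_invalid("`corpus` must be a non-empty list of token vectors")
  }
  if (d < 2 || d != round(d)) stop_invalid("`d` must be an integer >= 2")
  if (w < 1 || w != round(w)) stop_invalid("`w` must be an integer >= 1")
  if (min_count < 1) stop_invalid("`min_count` must be >= 1")

  flat <- unlist(corpus, use.names = FALSE)
  if (length(flat) == 0L) stop_invalid("`corpus` contains no tokens")
  lens <- lengths(corpus)
  freq <- table(flat)
  keep <- names(freq)[freq >= min_count]
  if (length(keep) == 0L) {
    stop_invalid("no token reaches min_count = %d", min_count)
  }
  # vocabulary ordered by descending frequency, ties lexicographic
  keep <- keep[order(-as.integer(freq[keep]), keep)]
  idx <- match(flat, keep)  # NA for dropped tokens

  ok <- !is.na(idx)
  sent_id <- rep.int(seq_along(lens), lens)[ok]
  tok <- idx[ok] - 1L
  sent_len <- tabulate(sent_id, nbins = length(lens))
  nonempty <- sent_len > 0L
  counts <- as.numeric(freq[keep])

  vec <- sgns_train(tok, sent_len[nonempty], length(keep), counts,
                    as.integer(d), as.integer(w), as.integer(epochs),
                    as.integer(negative), alpha, as.integer(seed))
  rownames(vec) <- keep
  structure(
    list(vectors = vec, counts = stats::setNames(counts, keep),
         d = d, w = w, epochs = epochs, min_count = min_count,
         negative = negative, alpha = alpha, seed = seed),
    class = "skipgram_model"
  )
}

#' @export
print.skipgram_model <- function(x, ...) {
  cat(sprintf("<skipgram_model> %d words x %d dims (w = %d, epochs = %d)\n",
              nrow(x$vectors), x$d, x$w, x$epochs))
  invisible(x)
}

#' Cosine similarity of two vectors
#'
#' `u . v / (||u|| ||v||)`, in `[-1, 1]`.
#'
#' @param u,v numeric vectors of equal length, both nonzero.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop_invalid("`u` and `v` differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop_invalid("cosine similarity undefined for a zero vector")
  }
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Rank vocabulary terms by embedding similarity to seed illness terms
#'
#' Scores every non-seed vocabulary word by its cosine similarity to the seed
#' terms — aggregated by max (default: a term strongly tied to any one
#' illness qualifies) or mean — and sorts descending, ties broken
#' lexicographically.
#'
#' @param model a `skipgram_model`.
#' @param seed_terms seed words; all must be in the vocabulary. Default:
#'   the three primary illness terms asthma, copd, smoking.
#' @param aggregation `"max"` or `"mean"` over seeds.
#' @return a `ranked_terms` data.frame (`rank`, `term`, `score`) with the
#'   seeds stored in `attr(, "seed_terms")`.
#' @export
rank_by_similarity <- function(model, seed_terms = c("asthma", "copd", "smoking"),
                               aggregation = c("max", "mean")) {
  stopifnot(inherits(model, "skipgram_model"))
  aggregation <- match.arg(aggregation)
  vocab <- rownames(model$vectors)
  missing <- setdiff(seed_terms, vocab)
  if (length(missing)) {
    stop_invalid("seed term(s) not in vocabulary: %s",
                 paste(missing, collapse = ", "))
  }
  terms <- setdiff(vocab, seed_terms)
  v <- model$vectors
  norms <- sqrt(rowSums(v^2))
  norms[norms == 0] <- NA_real_
  vn <- v / norms
  sims <- vn[terms, , drop = FALSE] %*% t(vn[seed_terms, , drop = FALSE])
  score <- if (aggregation == "max") {
    apply(sims, 1L, max)
  } else {
    rowMeans(sims)
  }
  score <- pmin(1, pmax(-1, score))
  ord <- order(-score, terms)
  out <- data.frame(rank = seq_along(ord), term = terms[ord],
                    score = unname(score[ord]), stringsAsFactors = FALSE)
  structure(out, class = c("ranked_terms", "data.frame"),
            seed_terms = seed_terms, aggregation = aggregation)
}

#' Select keywords by the stop-at-first-non-disease-term rule
#'
#' Walks the similarity ranking from the top and keeps terms until the first
#' one labelled non-disease, returning the maximal all-relevant prefix with
#' categories taken from the label source.
#'
#' @param ranked a `ranked_terms` object.
#' @param relevance_labels named character vector covering every ranked term:
#'   values `"symptom"`, `"disease"`, `"medication"` or `"smoking"` mark a
#'   term as disease-related (with its category); `"none"` or `NA` mark it
#'   non-disease.
#' @return a `keyword_set` (possibly empty).
#' @export
select_keywords <- function(ranked, relevance_labels) {
  stopifnot(inherits(ranked, "ranked_terms"))
  unlabeled <- setdiff(ranked$term, names(relevance_labels))
  if (length(unlabeled)) {
    stop_invalid("unlabeled term(s): %s",
                 paste(head(unlabeled, 5), collapse = ", "))
  }
  lab <- relevance_labels[ranked$term]
  relevant <- !is.na(lab) & lab %in% c("symptom", "disease", "medication", "smoking")
  first_no <- match(FALSE, relevant, nomatch = length(relevant) + 1L)
  keep <- seq_len(first_no - 1L)
  if (length(keep) == 0L) {
    return(keyword_set(character(0), character(0)))
  }
  keyword_set(ranked$term[keep], unname(lab[keep]))
}

#' Augment a keyword set with a curated medication list
#'
#' Adds medication terms (e.g. from the medical literature) under category
#' `medication`. Terms already present keep their existing category — first
#' assignment wins, so embedding-derived categories take precedence.
#'
#' @param base a `keyword_set`.
#' @param medication_terms character vector of lowercase medication names.
#' @return a `keyword_set`.
#' @export
augment_with_medications <- function(base, medication_terms) {
  stopifnot(inherits(base, "keyword_set"))
  medication_terms <- as.character(medication_terms)
  if (any(medication_terms != tolower(medication_terms))) {
    stop_invalid("medication terms must be lowercase")
  }
  new <- setdiff(unique(medication_terms), base$keyword)
  keyword_set(c(base$keyword, new),
              c(base$category, rep("medication", length(new))))
}
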