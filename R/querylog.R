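#' Construct a query log
#'
#' A query log stores user-attributed, tract-assigned search events. For
#' scalability the tokens are kept in long form (one row per token) next to a
#' per-event table, rather than as nested lists.
#'
#' @param events data.frame with columns `event_id` (integer, unique),
#'   `user_id`, `tract_id`.
#' @param tokens data.frame with columns `event_id`, `token`; every event
#'   must have at least one token.
#' @return a `query_log` (list of two data.tables, keyed by `event_id`).
#' @export
query_log <- function(events, tokens) {
  events <- data.table::as.data.table(events)
  tokens <- data.table::as.data.table(tokens)
  need_e <- c("event_id", "user_id", "tract_id")
  if (!all(need_e %in% names(events))) {
    stop_invalid("`events` needs columns %s", paste(need_e, collapse = ", "))
  }
  if (!all(c("event_id", "token") %in% names(tokens))) {
    stop_invalid("`tokens` needs columns event_id, token")
  }
  if (anyDuplicated(events$event_id)) stop_invalid("event ids must be unique")
  orphan <- setdiff(events$event_id, unique(tokens$event_id))
  if (length(orphan)) {
    stop_invalid("%d event(s) have no tokens", length(orphan))
  }
  data.table::setkey(events, event_id)
  data.table::setkey(tokens, event_id)
  structure(list(events = events, tokens = tokens), class = "query_log")
}

#' @export
print.query_log <- function(x, ...) {
  cat(sprintf("<query_log> %d events, %d users, %d tracts, %d tokens\n",
              nrow(x$events), length(unique(x$events$user_id)),
              length(unique(x$events$tract_id)), nrow(x$tokens)))
  invisible(x)
}

#' Per-tract event and unique-user counts of a query log
#'
#' @param log a `query_log`.
#' @return data.frame with `tract_id`, `n_events`, `n_users`.
#' @export
tract_activity <- function(log) {
  stopifnot(inherits(log, "query_log"))
  ev <- log$events
  out <- ev[, list(n_events = .N,
                   n_users = data.table::uniqueN(user_id)),
            by = "tract_id"]
  data.table::setorder(out, tract_id)
  as.data.frame(out)
}

#' Convert a query log to one row per event with space-joined tokens
#' @param x a `query_log`.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.query_log <- function(x, row.names = NULL, optional = FALSE, ...) {
  tok <- x$tokens[, list(query = paste(token, collapse = " ")),
                  by = "event_id"]
  out <- merge(x$events, tok, by = "event_id")
  data.table::setorder(out, event_id)
  data.frame(out, stringsAsFactors = FALSE)
}

#' Query corpus as a list of token vectors
#'
#' The representation consumed by [train_embedding()].
#' @param log a `query_log`.
#' @return unnamed list; one character vector of tokens per event.
#' @export
corpus_from_log <- function(log) {
  stopifnot(inherits(log, "query_log"))
  tok <- log$tokens
  unname(split(tok$token, tok$event_id))
}

#' Restrict a query log to a set of tracts
#'
#' Drops all events (and their tokens) generated from tracts outside `ids`;
#' used after tract filtering so excluded tracts contribute nothing.
#'
#' @param log a `query_log`.
#' @param ids character vector of tract ids to keep.
#' @return a `query_log`.
#' @export
subset_query_log <- function(log, ids) {
  stopifnot(inherits(log, "query_log"))
  ev <- log$events[log$events$tract_id %in% ids]
  tok <- log$tokens[log$tokens$event_id %in% ev$event_id]
  query_log(ev, tok)
}

#' Generate a synthetic geo-located query log
#'
#' Emulates a year of search activity over a synthetic city. Each tract gets
#' `max(1, round(users_per_capita * population))` users; each user issues a
#' Poisson(`queries_per_user`) number of queries. A query is a short bag of
#' background tokens (Zipf-weighted) and, with probability
#' `p_i = base_rate * (1 + signal_strength * prevalence_i / 100)`,
#' carries one or more disease keywords drawn by category mix — encoding the
#' premise that residents of higher-prevalence tracts search illness terms
#' more often. With `signal_strength = 0` the keyword rate is flat across
#' tracts.
#'
#' @param tracts a `tract_set`.
#' @param prevalence a `prevalence_table`; `p_i` uses the mean across its
#'   outcome columns (both synthetic outcomes share one query signal).
#' @param vocab a `keyword_set` of disease keywords.
#' @param background_vocab character vector of background words, disjoint
#'   from `vocab`.
#' @param users_per_capita fraction of tract population issuing queries.
#' @param queries_per_user Poisson mean queries per user.
#' @param signal_strength non-negative slope of the keyword rate on
#'   prevalence; 0 removes the signal.
#' @param base_rate baseline probability that a query is disease-related.
#' @param bg_tokens_mean Poisson mean of extra background tokens per query
#'   (every query has at least one token).
#' @param extra_keywords_mean Poisson mean of additional keywords co-occurring
#'   in a disease-related query (models users searching several related terms
#'   at once; gives the embedding a co-occurrence signal).
#' @param category_mix named positive weights over the four keyword
#'   categories.
#' @param seed integer RNG seed.
#' @return a `query_log`.
#' @export
generate_queries <- function(tracts, prevalence, vocab = default_keywords(),
                             background_vocab = default_background_vocab(),
                             users_per_capita = 0.05, queries_per_user = 20,
                             signal_strength = 2, base_rate = 0.05,
                             bg_tokens_mean = 3, extra_keywords_mean = 0.35,
                             category_mix = c(symptom = 0.35, disease = 0.30,
                                              medication = 0.20,
                                              smoking = 0.15),
                             seed = 1) {
  stopifnot(inherits(tracts, "tract_set"), inherits(vocab, "keyword_set"))
  overlap <- intersect(vocab$keyword, background_vocab)
  if (length(overlap)) {
    stop_invalid("vocab and background_vocab overlap: %s",
                 paste(head(overlap, 5), collapse = ", "))
  }
  if (signal_strength < 0) stop_invalid("`signal_strength` must be >= 0")
  if (queries_per_user <= 0) stop_invalid("`queries_per_user` must be > 0")
  tr <- tracts$tracts
  prev <- as.data.frame(prevalence)
  prev <- prev[match(tr$tract_id, prev$tract_id), , drop = FALSE]
  if (anyNA(prev$tract_id)) stop_invalid("prevalence missing some tracts")
  outcome_cols <- setdiff(names(prev), "tract_id")
  p_mean <- rowMeans(prev[, outcome_cols, drop = FALSE])
  p_disease <- pmin(1, base_rate * (1 + signal_strength * p_mean / 100))

  kw_weights <- category_mix[vocab$category]
  kw_weights <- kw_weights / ave(kw_weights, vocab$category, FUN = length)
  bg_weights <- 1 / seq_along(background_vocab)  # Zipf

  with_seed(seed, {
    n_users_tr <- pmax(1L, as.integer(round(users_per_capita * tr$population)))
    user_tract_idx <- rep.int(seq_len(nrow(tr)), n_users_tr)
    n_users <- length(user_tract_idx)
    user_ids <- sprintf("U%07d", seq_len(n_users))
    q_per_user <- rpois(n_users, queries_per_user)
    ev_user <- rep.int(seq_len(n_users), q_per_user)
    n_ev <- length(ev_user)
    if (n_ev == 0L) stop_invalid("no queries generated; increase rates")
    ev_tract_idx <- user_tract_idx[ev_user]

    n_bg <- 1L + rpois(n_ev, bg_tokens_mean)
    is_dis <- rbinom(n_ev, 1L, p_disease[ev_tract_idx]) == 1L
    n_kw <- integer(n_ev)
    n_kw[is_dis] <- 1L + rpois(sum(is_dis), extra_keywords_mean)

    bg_tok <- background_vocab[sample.int(length(background_vocab),
                                          sum(n_bg), replace = TRUE,
                                          prob = bg_weights)]
    kw_tok <- vocab$keyword[sample.int(nrow(vocab), sum(n_kw),
                                       replace = TRUE, prob = kw_weights)]

    tok <- data.table::data.table(
      event_id = c(rep.int(seq_len(n_ev), n_bg), rep.int(seq_len(n_ev), n_kw)),
      token = c(bg_tok, kw_tok)
    )
    # shuffle token order within each event
    tok <- tok[order(tok$event_id, runif(nrow(tok)))]

    events <- data.table::data.table(
      event_id = seq_len(n_ev),
      user_id = user_ids[ev_user],
      tract_id = tr$tract_id[ev_tract_idx]
    )
    query_log(events, tok)
  })
}
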