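# Shared fixtures, all generated in code.

# a small city reused across tests (cached per session)
small_city <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_city(n_tracts = 60, seed = 42,
                              users_per_capita = 0.05, queries_per_user = 10)
    }
    cache
  }
})

# query log built explicitly from event token lists
log_from_events <- function(events) {
  ev <- data.frame(
    event_id = seq_along(events),
    user_id = vapply(events, function(e) e$user_id, ""),
    tract_id = vapply(events, function(e) e$tract_id, ""),
    stringsAsFactors = FALSE
  )
  tok <- data.frame(
    event_id = rep.int(ev$event_id,
                       vapply(events, function(e) length(e$tokens), 0L)),
    token = unlist(lapply(events, function(e) e$tokens)),
    stringsAsFactors = FALSE
  )
  query_log(ev, tok)
}

random_events <- function(n, ids, vocab, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(user_id = sprintf("u%03d", sample.int(max(2L, n %/% 2L), 1L)),
           tract_id = sample(ids, 1L),
           tokens = sample(vocab, sample(1:5, 1L), replace = TRUE))
    })
  })
}

# planted-synonym corpus: related terms share query contexts with the seed
# illness terms; background queries use everyday words only
planted_corpus <- function(n_queries = 2000, seed = 1,
                           related = c("wheezing", "inhaler", "bronchitis",
                                       "nebulizer", "vape", "nicotine",
                                       "cough", "emphysema", "albuterol",
                                       "phlegm")) {
  seeds <- c("asthma", "copd", "smoking")
  bg <- default_background_vocab(100)
  withr::with_seed(seed, {
    lapply(seq_len(n_queries), function(i) {
      if (runif(1) < 0.4) {
        health <- sample(c(seeds, related), sample(2:4, 1L))
        c(health, sample(bg, sample(1:2, 1L)))
      } else {
        sample(bg, sample(3:6, 1L), replace = TRUE)
      }
    })
  })
}

# a raster built directly from a class-name matrix (row 1 = south edge)
raster_from_matrix <- function(class_names, cell_km = 1, origin = c(0, 0)) {
  legend <- landcover_classes()
  codes <- matrix(legend$code[match(class_names, legend$class)],
                  nrow(class_names), ncol(class_names))
  structure(list(grid = codes, cell_km = cell_km,
                 origin = c(x = origin[1], y = origin[2]), legend = legend),
            class = "landcover_raster")
}

# labels marking the generator's vocabulary as relevant, all else "none"
labels_for <- function(ranked, vocab = default_keywords()) {
  lab <- stats::setNames(rep("none", nrow(ranked)), ranked$term)
  hit <- ranked$term %in% vocab$keyword
  lab[ranked$term[hit]] <- vocab$category[match(ranked$term[hit], vocab$keyword)]
  lab
}
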