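test_that("vocabulary covers the distinct tokens of a tiny corpus", {
  corpus <- rep(list(c("red", "green", "blue")), 10)
  m <- train_embedding(corpus, d = 8, w = 2, epochs = 1, min_count = 1,
                       seed = 1)
  expect_setequal(rownames(m$vectors), c("red", "green", "blue"))
  expect_equal(ncol(m$vectors), 8L)
})

test_that("min_count drops rare tokens", {
  corpus <- c(rep(list(c("common", "words", "here")), 10),
              list(c("rare", "common")))
  m <- train_embedding(corpus, d = 4, w = 2, epochs = 1, min_count = 5,
                       seed = 1)
  expect_false("rare" %in% rownames(m$vectors))
  expect_true("common" %in% rownames(m$vectors))
})

test_that("shared-context tokens end up closer than unrelated ones", {
  # A and B always appear in identical contexts; C lives elsewhere
  withr::with_seed(1, {
    ctx <- replicate(2000, sample(sprintf("ctx%02d", 1:20), 3), simplify = FALSE)
    corpus <- c(
      lapply(ctx[1:1000], function(cc) c(sample(c("aaa", "bbb"), 1), cc)),
      lapply(ctx[1001:2000], function(cc)
        c("ccc", sample(sprintf("other%02d", 1:20), 3)))
    )
  })
  m <- train_embedding(corpus, d = 30, w = 4, epochs = 5, min_count = 5,
                       seed = 2)
  ab <- cosine_similarity(m$vectors["aaa", ], m$vectors["bbb", ])
  ac <- cosine_similarity(m$vectors["aaa", ], m$vectors["ccc", ])
  expect_gt(ab, ac)
})

test_that("training is deterministic given a seed", {
  corpus <- planted_corpus(300, seed = 5)
  a <- train_embedding(corpus, d = 16, w = 3, epochs = 2, seed = 7)
  b <- train_embedding(corpus, d = 16, w = 3, epochs = 2, seed = 7)
  expect_identical(a$vectors, b$vectors)
})

test_that("embedding rejects invalid parameters", {
  expect_error(train_embedding(list(), d = 10), "non-empty")
  expect_error(train_embedding(list(c("a", "b")), d = 1), "d")
  expect_error(train_embedding(list(c("a", "b")), d = 10, w = 0), "w")
  expect_error(train_embedding(list("a"), d = 10, min_count = 5), "min_count")
})

test_that("cosine similarity matches closed forms and rejects zero vectors", {
  v <- c(0.3, -1.2, 2.5)
  expect_equal(cosine_similarity(v, v), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2),
               tolerance = 1e-8)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "length")
})

test_that("ranking is a permutation with deterministic tie handling", {
  corpus <- planted_corpus(500, seed = 2)
  m <- train_embedding(corpus, d = 20, w = 4, epochs = 3, seed = 1)
  rk <- rank_by_similarity(m)
  expect_setequal(rk$term,
                  setdiff(rownames(m$vectors), c("asthma", "copd", "smoking")))
  expect_false(anyDuplicated(rk$term) > 0)
  expect_true(all(diff(rk$score) <= 1e-12))
  expect_true(all(rk$score >= -1 & rk$score <= 1))
  # identical vectors -> identical scores -> adjacent lexicographic ranks
  m2 <- m
  m2$vectors <- rbind(m2$vectors, zzz_twin = m2$vectors[rk$term[1], ])
  rk2 <- rank_by_similarity(m2)
  pair <- which(rk2$term %in% c(rk$term[1], "zzz_twin"))
  expect_equal(diff(pair), 1L)
  expect_equal(rk2$term[pair], sort(c(rk$term[1], "zzz_twin")))
})

test_that("seeds-only vocabulary yields an empty ranking, absent seeds error", {
  corpus <- rep(list(c("asthma", "copd", "smoking")), 20)
  m <- train_embedding(corpus, d = 4, w = 2, epochs = 1, min_count = 1,
                       seed = 1)
  rk <- rank_by_similarity(m)
  expect_equal(nrow(rk), 0L)
  expect_error(rank_by_similarity(m, seed_terms = c("asthma", "zebra")),
               "zebra")
})

test_that("mean aggregation is available and differs from max", {
  corpus <- planted_corpus(500, seed = 3)
  m <- train_embedding(corpus, d = 20, w = 4, epochs = 3, seed = 1)
  rk_max <- rank_by_similarity(m, aggregation = "max")
  rk_mean <- rank_by_similarity(m, aggregation = "mean")
  s_max <- rk_max$score[match(rk_max$term[1], rk_max$term)]
  s_mean <- rk_mean$score[match(rk_max$term[1], rk_mean$term)]
  expect_gte(s_max, s_mean)
})

test_that("the stop rule returns the maximal all-relevant prefix", {
  rk <- structure(
    data.frame(rank = 1:4, term = c("t1", "t2", "t3", "t4"),
               score = c(0.9, 0.8, 0.7, 0.6), stringsAsFactors = FALSE),
    class = c("ranked_terms", "data.frame"),
    seed_terms = "asthma")
  lab <- c(t1 = "symptom", t2 = "disease", t3 = "none", t4 = "medication")
  sel <- select_keywords(rk, lab)
  expect_equal(sel$keyword, c("t1", "t2"))
  expect_equal(sel$category, c("symptom", "disease"))
  # first term irrelevant -> empty selection
  expect_equal(nrow(select_keywords(rk, c(t1 = "none", lab[-1]))), 0L)
  # all relevant -> everything selected
  all_yes <- c(t1 = "symptom", t2 = "disease", t3 = "smoking",
               t4 = "medication")
  expect_equal(nrow(select_keywords(rk, all_yes)), 4L)
  expect_error(select_keywords(rk, lab[-2]), "unlabeled")
})

test_that("stop-rule output length matches a brute-force scan", {
  withr::with_seed(4, {
    for (i in 1:20) {
      n <- sample(1:30, 1)
      relevant <- runif(n) < 0.6
      rk <- structure(
        data.frame(rank = seq_len(n), term = sprintf("w%02d", seq_len(n)),
                   score = sort(runif(n), decreasing = TRUE),
                   stringsAsFactors = FALSE),
        class = c("ranked_terms", "data.frame"), seed_terms = "asthma")
      lab <- stats::setNames(ifelse(relevant, "disease", "none"), rk$term)
      expect_equal(nrow(select_keywords(rk, lab)),
                   oracle_prefix_length(relevant))
    }
  })
})
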