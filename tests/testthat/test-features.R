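fts <- generate_tracts(9, region_size = 6, jitter = 0, seed = 1)
ids9 <- fts$tracts$tract_id
kw3 <- keyword_set(c("cough", "asthma", "inhaler"),
                   c("symptom", "disease", "medication"))

test_that("normalized counts match hand-built event lists", {
  events <- c(
    lapply(1:2, function(i) list(user_id = "u1", tract_id = ids9[1],
                                 tokens = c("cough", "weather"))),
    lapply(3:10, function(i) list(user_id = "u2", tract_id = ids9[1],
                                  tokens = c("news", "pizza"))),
    list(list(user_id = "u3", tract_id = ids9[2],
              tokens = c("asthma", "asthma", "cough")))
  )
  log <- log_from_events(events)
  nc <- normalized_counts(log, kw3, fts)
  expect_equal(nc$cough[nc$tract_id == ids9[1]], 0.2)      # 2 of 10
  expect_equal(nc$asthma[nc$tract_id == ids9[1]], 0)       # absent
  expect_equal(nc$asthma[nc$tract_id == ids9[2]], 1)       # every event
  expect_equal(nc$cough[nc$tract_id == ids9[2]], 1)
  # repeated token in one query counts once
  expect_true(all(as.matrix(as.data.frame(nc)[, kw3$keyword]) <= 1))
  # zero-event tracts are flagged and zero-filled
  expect_setequal(attr(nc, "zero_event_tracts"), ids9[-(1:2)])
  expect_true(all(as.data.frame(nc)[nc$tract_id %in% ids9[3:9],
                                    kw3$keyword] == 0))
})

test_that("normalized counts reject unknown tracts", {
  log <- log_from_events(list(list(user_id = "u", tract_id = "T9999",
                                   tokens = "cough")))
  expect_error(normalized_counts(log, kw3, fts), "unknown tract")
})

test_that("category sums add the three aggregate columns", {
  df <- data.frame(tract_id = ids9[1:2],
                   cough = c(0.1, 0.05), asthma = c(0.3, 0),
                   inhaler = c(0.2, 0.1))
  ft <- feature_table(df, "query")
  out <- category_sums(ft, kw3)
  expect_equal(out$sum_symptoms, c(0.1, 0.05))
  expect_equal(out$sum_diseases, c(0.3, 0))
  expect_equal(out$sum_medications, c(0.2, 0.1))
  # multi-member category: hand sum
  kw4 <- keyword_set(c("cough", "wheezing"), c("symptom", "symptom"))
  df4 <- data.frame(tract_id = "A", cough = 0.1, wheezing = 0.05)
  out4 <- category_sums(feature_table(df4, "query"), kw4)
  expect_equal(out4$sum_symptoms, 0.15)
  expect_equal(out4$sum_diseases, 0)  # empty category -> zeros
})

test_that("census features pass the 20 proportions through unchanged", {
  cens <- generate_census(fts, seed = 1)
  cf <- census_features(cens, fts)
  expect_equal(length(setdiff(names(cf), "tract_id")), 20L)
  expect_equal(cf$poverty, cens$poverty)
  expect_equal(unname(attr(cf, "provenance")["poverty"]), "census")
  missing <- cens[-1, ]
  class(missing) <- class(cens)
  expect_error(census_features(missing, fts), ids9[1])
})

test_that("merge_features concatenates, aligns, and rejects conflicts", {
  a <- feature_table(data.frame(tract_id = ids9, f1 = runif(9)), "query")
  b <- feature_table(data.frame(tract_id = rev(ids9), f2 = runif(9)),
                     "landcover")
  out <- merge_features(list(a, b))
  expect_equal(setdiff(names(out), "tract_id"), c("f1", "f2"))
  # row alignment honoured despite reversed input order
  expect_equal(out$f2[out$tract_id == ids9[1]], b$f2[b$tract_id == ids9[1]])
  # duplicate columns rejected
  expect_error(merge_features(list(a, a)), "duplicate")
  # mismatched tract sets rejected
  short <- feature_table(data.frame(tract_id = ids9[-1], f3 = runif(8)),
                         "query")
  expect_error(merge_features(list(a, short)), "different tract sets")
})

test_that("the state feature is one integer-coded column", {
  a <- feature_table(data.frame(tract_id = ids9, f1 = runif(9)), "query")
  out <- merge_features(list(a), state_feature = TRUE, tracts = fts)
  expect_true("state" %in% names(out))
  expect_equal(length(unique(out$state)), 4L)
  expect_true(is.numeric(out$state))
  codes <- attr(out, "state_codes")
  expect_setequal(names(codes), unique(fts$tracts$state_code))
})

test_that("point assignment matches the brute-force containment scan", {
  ts <- generate_tracts(36, region_size = 12, jitter = 0.3, seed = 5)
  withr::with_seed(6, {
    pts <- cbind(runif(1000, 0, 12), runif(1000, 0, 12))
  })
  got <- assign_points_to_tracts(pts, ts)
  want <- oracle_assign_points(pts, ts)
  expect_equal(as.character(got), want)
})

test_that("centroids map to their own tract and edge points break ties low", {
  ts <- generate_tracts(9, region_size = 6, jitter = 0, seed = 1)
  got <- assign_points_to_tracts(
    cbind(ts$tracts$centroid_x, ts$tracts$centroid_y), ts)
  expect_equal(as.character(got), ts$tracts$tract_id)
  # midpoint of the shared vertical edge between the first two grid tracts
  edge_pt <- matrix(c(2, 1), 1)
  owner <- assign_points_to_tracts(edge_pt, ts)
  both <- oracle_assign_points(edge_pt, ts)
  expect_equal(as.character(owner), both)  # lexicographically smallest
  # far outside point is unassigned and counted
  expect_message(out <- assign_points_to_tracts(matrix(c(99, 99), 1), ts),
                 "outside")
  expect_true(is.na(out[1]))
  expect_equal(attr(out, "n_unassigned"), 1L)
})
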