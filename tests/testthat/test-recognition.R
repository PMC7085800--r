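test_that("weight and vote-count constraints are enforced", {
  expect_error(recognition_config(w1 = 0.2, w2 = 0.7), "2\\*w1 \\+ w2")
  expect_error(recognition_config(w1 = 0.3, w2 = 0.4), "2\\*w1 <= w2")
  expect_error(recognition_config(n = 0), "positive")
  expect_error(recognition_config(k = -2), "positive integer")
  cfg <- recognition_config(w1 = 0.1, w2 = 0.8, n = 3)
  expect_s3_class(cfg, "recognition_config")
})

test_that("the Levenshtein ratio has the forced boundary values", {
  expect_equal(levenshtein_ratio(c("A", "B", "C"), c("A", "B", "C")), 1)
  # disjoint alphabets: every alignment costs insert+delete or a
  # substitution at cost 2, so ldist = m + n and the ratio is 0
  expect_equal(levenshtein_ratio(c("A", "B"), c("C", "D", "E")), 0)
  expect_error(levenshtein_ratio(character(0), "A"), "non-empty")
})

test_that("the worked-example sequence pair scores one half", {
  acts <- segment_activities(table1_fixture())
  r <- levenshtein_ratio(acts$sq[[1]], acts$sq[[2]])
  expect_equal(r, oracle_lev_ratio(acts$sq[[1]], acts$sq[[2]]))
  expect_equal(r, 0.5)
})

test_that("token-level comparison ignores character overlap of ids", {
  # as characters, M004/M005 share 3 of 4 symbols; as tokens they are
  # simply different
  expect_equal(levenshtein_ratio("M004", "M005"), 0)
})

test_that("the ratio matches the DP oracle for both substitution costs", {
  withr::with_seed(123, {
    pairs <- replicate(60, list(a = random_seq(12), b = random_seq(12)),
                       simplify = FALSE)
  })
  for (p in pairs) {
    expect_equal(levenshtein_ratio(p$a, p$b),
                 oracle_lev_ratio(p$a, p$b))
    expect_equal(levenshtein_ratio(p$a, p$b, sub_cost = 1),
                 oracle_lev_ratio(p$a, p$b, sub_cost = 1))
  }
})

test_that("similarity of an instance with itself is the weight total", {
  a <- list(bt = 5, et = 6, sq = c("M001", "M002"))
  for (w1 in c(0, 0.1, 0.15)) {
    cfg <- recognition_config(w1 = w1, w2 = 1 - 2 * w1)
    expect_equal(similarity(a, a, cfg), 2 * w1 + (1 - 2 * w1))
    expect_equal(similarity(a, a, cfg), 1)
  }
})

test_that("the twelve-hour disjoint case gives the bare time credit", {
  cfg <- recognition_config(w1 = 0.15, w2 = 0.7)
  a <- list(bt = 2, et = 3, sq = c("A", "B"))
  t <- list(bt = 14, et = 15, sq = c("C", "D"))
  expect_equal(similarity(a, t, cfg), 0.15)
})

test_that("similarity is symmetric, bounded, and monotone in time gaps", {
  cfg <- recognition_config()
  withr::with_seed(31, {
    for (i in 1:25) {
      a <- list(bt = sample(0:23, 1), et = sample(0:23, 1),
                sq = random_seq(8))
      t <- list(bt = sample(0:23, 1), et = sample(0:23, 1),
                sq = random_seq(8))
      s <- similarity(a, t, cfg)
      expect_equal(s, similarity(t, a, cfg))
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
  })
  base <- list(bt = 10, et = 10, sq = c("A", "B"))
  sims <- vapply(0:10, function(gap) {
    similarity(base, list(bt = 10 + gap, et = 10, sq = c("A", "B")), cfg)
  }, numeric(1))
  expect_true(all(diff(sims) <= 0))
})

toy_train <- function() {
  acts <- activities_from(list(
    list("Wake",  6,  6, c("M001", "M002")),
    list("Wake",  6,  7, c("M001", "M002", "M003")),
    list("Lunch", 12, 12, c("M010", "M011")),
    list("Lunch", 12, 13, c("M010", "M011", "M012")),
    list("TV",    20, 21, c("M020", "M021")),
    list("TV",    20, 20, c("M020", "M021", "M020"))
  ))
  acts
}

activities_from <- function(rows) {
  tibble::tibble(
    label = vapply(rows, `[[`, character(1), 1),
    bt = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
    et = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    sq = lapply(rows, `[[`, 4)
  )
}

test_that("an exact training copy wins with a single vote", {
  train <- toy_train()
  model <- fit_kmeans(time_points(train), 3, seed = 1)
  cfg <- recognition_config(n = 1)
  q <- list(bt = 12, et = 12, sq = c("M010", "M011"))
  expect_equal(recognize(train, model, q, cfg)$label, "Lunch")
})

test_that("disjoint time windows and vocabularies classify perfectly", {
  train <- toy_train()
  model <- fit_kmeans(time_points(train), 3, seed = 1)
  cfg <- recognition_config(n = 2)
  for (i in seq_len(nrow(train))) {
    expect_equal(recognize(train, model, train[i, ], cfg)$label,
                 train$label[i])
  }
})

test_that("a split vote falls to the label with greater summed similarity", {
  train <- activities_from(list(
    list("X", 10, 10, c("A", "B", "C")),
    list("X", 10, 10, c("A", "B", "D")),
    list("Y", 10, 10, c("A", "E", "F")),
    list("Y", 10, 10, c("A", "E", "G"))
  ))
  model <- fit_kmeans(time_points(train), 1, seed = 1)
  cfg <- recognition_config(n = 4)
  # query closer to the X pair: shares two tokens with each X, one with
  # each Y, so the 2-2 vote resolves to X on summed similarity
  q <- list(bt = 10, et = 10, sq = c("A", "B", "H"))
  expect_equal(recognize(train, model, q, cfg)$label, "X")
})

test_that("an exact label tie resolves lexicographically", {
  train <- activities_from(list(
    list("B", 10, 10, c("A", "B")),
    list("A", 10, 10, c("A", "B"))
  ))
  model <- fit_kmeans(time_points(train), 1, seed = 1)
  cfg <- recognition_config(n = 2)
  q <- list(bt = 10, et = 10, sq = c("A", "B"))
  expect_equal(recognize(train, model, q, cfg)$label, "A")
})

test_that("an empty cluster falls back to the full training set", {
  train <- toy_train()
  model <- fit_kmeans(time_points(train), 3, seed = 1)
  # force a cluster with no members by re-pointing a centroid far away
  far <- which.min(colSums((t(model$centroids) - c(3, 3))^2))
  model$centroids[far, ] <- c(3, 3)
  model$assignment[model$assignment == far] <-
    setdiff(seq_len(model$k), far)[1]
  q <- list(bt = 3, et = 3, sq = c("M001", "M002"))
  expect_warning(res <- recognize(train, model, q,
                                  recognition_config(n = 1)),
                 "full training set")
  expect_equal(res$label, "Wake")
})

test_that("a cluster smaller than n votes with all its members", {
  train <- toy_train()
  model <- fit_kmeans(time_points(train), 3, seed = 1)
  q <- list(bt = 6, et = 6, sq = c("M001", "M002"))
  res <- recognize(train, model, q, recognition_config(n = 5))
  expect_lte(nrow(res$neighbours), 5)
  expect_equal(res$label, "Wake")
})
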