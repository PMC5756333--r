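test_that("sample QC statistics count totals, detections and dropouts", {
  m <- expr_matrix(cbind(c(0, 0, 5, 5), c(1, 1, 1, 1)),
                   sprintf("g%d", 1:4), c("A", "B"))
  qc <- sample_qc_stats(m)
  expect_equal(qc$total_counts, c(10, 4))
  expect_equal(qc$detected_features, c(2, 4))
  expect_equal(qc$dropout_rate, c(0.5, 0))

  zero <- expr_matrix(cbind(c(0, 0), c(1, 2)), c("g1", "g2"), c("A", "B"))
  qz <- sample_qc_stats(zero)
  expect_equal(qz$total_counts[1], 0)
  expect_equal(qz$detected_features[1], 0)
  expect_equal(qz$dropout_rate[1], 1)

  # identity: detected + zeros = n_features for every sample
  mm <- random_counts(30, 6, seed = 8)
  q <- sample_qc_stats(mm)
  expect_equal(q$dropout_rate * 30 + q$detected_features, rep(30, 6))

  sf <- size_factors_median_ratio(random_counts(30, 6, seed = 8,
                                                zero_free = TRUE))
  expect_true("size_factor" %in%
                names(sample_qc_stats(mm, sf)))
})

test_that("feature filtering applies expression rules with list overrides", {
  m <- expr_matrix(rbind(c(6, 6), c(6, 0), c(0, 0)),
                   c("g1", "g2", "g3"), c("A", "B"))
  res <- filter_features(m, feature_criteria(min_count = 5, min_samples = 2))
  expect_identical(feature_ids(res$matrix), "g1")
  expect_setequal(res$removed_ids, c("g2", "g3"))
  expect_identical(sample_ids(res$matrix), c("A", "B"))

  # empty criteria = identity
  res0 <- filter_features(m, feature_criteria())
  expect_identical(unclass(res0$matrix), unclass(m))

  # keep_list overrides a harsh expression filter
  res_keep <- filter_features(m, feature_criteria(min_count = 100,
                                                  min_samples = 1,
                                                  keep_list = "g3"))
  expect_identical(feature_ids(res_keep$matrix), "g3")

  expect_error(filter_features(m, feature_criteria(min_mean_expr = 1e9)),
               "all features removed")
  expect_warning(filter_features(m, feature_criteria(drop_list = "nope")),
                 "unknown feature")
})

test_that("feature filtering is idempotent and partitions the ID set", {
  m <- random_counts(50, 4, seed = 10)
  crit <- feature_criteria(min_count = 20, min_samples = 2)
  once <- filter_features(m, crit)
  twice <- filter_features(once$matrix, crit)
  expect_identical(unclass(twice$matrix), unclass(once$matrix))
  expect_length(twice$removed_ids, 0)
  expect_setequal(c(feature_ids(once$matrix), once$removed_ids),
                  feature_ids(m))
})

test_that("sample filtering removes samples outside active ranges", {
  m <- expr_matrix(rbind(c(5, 1), c(5, 0), c(0, 0), c(0, 0), c(0, 0),
                         c(5, 0), c(5, 0), c(5, 0), c(5, 0), c(5, 0)),
                   sprintf("g%d", 1:10), c("A", "B"))
  qc <- sample_qc_stats(m)
  expect_equal(qc$dropout_rate, c(0.3, 0.9))
  res <- filter_samples(m, sample_criteria(max_dropout = 0.6), qc)
  expect_identical(res$removed_ids, "B")
  expect_identical(feature_ids(res$matrix), feature_ids(m))

  # all-pass range is the identity
  qc2 <- sample_qc_stats(m)
  qc2$size_factor <- c(1, 1)
  res2 <- filter_samples(m, sample_criteria(size_factor_range = c(0.2, 5)), qc2)
  expect_length(res2$removed_ids, 0)

  res3 <- filter_samples(m, sample_criteria(drop_list = "A"))
  expect_identical(res3$removed_ids, "A")
  expect_error(filter_samples(m, sample_criteria(drop_list = c("A", "B"))),
               "all samples removed")
})

test_that("rank-frequency tables are normalized and sequentially ranked", {
  m <- expr_matrix(cbind(c(10, 30, 60), c(0, 0, 4)),
                   c("g1", "g2", "g3"), c("A", "B"))
  rf <- rank_frequency(m, "A")
  expect_equal(rf$rank, 1:3)
  expect_equal(rf$frequency, c(0.6, 0.3, 0.1))
  expect_identical(rf$feature_id, c("g3", "g2", "g1"))

  single <- rank_frequency(m, "B")
  expect_equal(nrow(single), 1)
  expect_equal(single$frequency, 1)

  for (seed in 1:5) {
    mm <- random_counts(40, 2, seed = seed)
    expect_equal(sum(rank_frequency(mm, "s01")$frequency), 1,
                 tolerance = 1e-12)
  }
  zero <- expr_matrix(cbind(c(0, 0), c(1, 1)), c("g1", "g2"), c("A", "B"))
  expect_error(rank_frequency(zero, "A"), "no positive count")
})

test_that("mean-variability uses the n-1 denominator and omits undefined CV", {
  m <- expr_matrix(rbind(c(1, 3), c(2, 2), c(0, 0)),
                   c("g1", "g2", "g3"), c("A", "B"), kind = "normalized")
  mv <- mean_variability(m)
  expect_identical(mv$feature_id, c("g1", "g2", "g3"))  # row order preserved
  expect_equal(mv$mean[1], 2)
  expect_equal(mv$sd[1], sqrt(2))
  expect_equal(mv$sd[2], 0)
  expect_true(is.na(mv$cv[3]))
})

test_that("feature query ranks correlated features correctly", {
  base <- c(1, 2, 3, 4, 5)
  m <- expr_matrix(rbind(i = base, j = 2 * base, k = -base + 6,
                         sq = base^2, flat = rep(1, 5)),
                   c("i", "j", "k", "sq", "flat"), sprintf("s%d", 1:5),
                   kind = "normalized")
  res <- suppressWarnings(feature_query(m, "i", "pearson"))
  expect_identical(res$feature_id[1], "j")
  expect_equal(res$correlation[1], 1)
  expect_identical(res$feature_id[nrow(res)], "k")
  expect_equal(res$correlation[nrow(res)], -1)
  expect_false("flat" %in% res$feature_id)
  expect_false("i" %in% res$feature_id)
  expect_warning(feature_query(m, "i"), "constant")

  sp <- suppressWarnings(feature_query(m, "i", "spearman"))
  expect_equal(sp$correlation[sp$feature_id == "sq"], 1)  # monotone copy

  expect_error(suppressWarnings(feature_query(m, "flat")), "constant")
  expect_error(feature_query(m, "nope"), "unknown feature")
})
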