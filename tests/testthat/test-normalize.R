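test_that("median-of-ratios reproduces the worked 3-gene example", {
  m <- worked_matrix_3x2()
  sf1 <- size_factors_median_ratio(m, min_detect_frac = 1)
  expect_equal(unname(sf1$factors), c(0.5, 2))
  sf05 <- size_factors_median_ratio(m, min_detect_frac = 0.5)
  expect_equal(unname(sf05$factors), c(0.5, 2))

  # pure scaling: column B = 2 x column A forces (1/sqrt(2), sqrt(2))
  a <- c(3, 7, 11, 2)
  m2 <- expr_matrix(cbind(a, 2 * a), sprintf("g%d", 1:4), c("A", "B"))
  sf <- size_factors_median_ratio(m2, 1)
  expect_equal(unname(sf$factors), c(1 / sqrt(2), sqrt(2)))
})

test_that("min_detect_frac = 1 equals the classic estimator on zero-free data", {
  for (seed in 1:5) {
    m <- random_counts(50, 4, seed = seed, zero_free = TRUE)
    mine <- size_factors_median_ratio(m, 1)$factors
    expect_equal(unname(mine), unname(classic_median_ratio(m)),
                 tolerance = 1e-12)
  }
  # cross-check against an established implementation of the classic method;
  # odd feature count so the median needs no interpolation (that reference
  # takes the median on the log scale, which only matches exactly at odd n)
  skip_if_not_installed("DESeq2")
  m <- random_counts(51, 4, seed = 42, zero_free = TRUE)
  ds <- DESeq2::estimateSizeFactorsForMatrix(unclass(m))
  ds <- ds / exp(mean(log(ds)))
  expect_equal(unname(size_factors_median_ratio(m, 1)$factors), unname(ds),
               tolerance = 1e-9)
})

test_that("median-of-ratios error paths are informative", {
  m <- expr_matrix(rbind(c(1, 0), c(0, 1)), c("g1", "g2"), c("A", "B"))
  expect_error(size_factors_median_ratio(m, 1), "lower min_detect_frac")
  m2 <- expr_matrix(rbind(c(1, 0), c(2, 0), c(3, 0)),
                    c("g1", "g2", "g3"), c("A", "B"))
  expect_error(size_factors_median_ratio(m2, 0.5), "'B'")
})

test_that("scaling one column by c scales its raw factor by c", {
  m <- random_counts(80, 4, seed = 11, zero_free = TRUE)
  c_scale <- 3.7
  v2 <- unclass(m); v2[, 2] <- v2[, 2] * c_scale
  m2 <- expr_matrix(v2, feature_ids(m), sample_ids(m))
  for (fn in list(function(x) size_factors_median_ratio(x, 1),
                  size_factors_upper_quartile)) {
    f1 <- fn(m)$factors
    f2 <- fn(m2)$factors
    ratio <- f2 / f1  # geometric-mean rescaling spreads c^(1/n) over samples
    expect_equal(unname(ratio[2] / ratio[1]), c_scale, tolerance = 1e-9)
    expect_equal(unname(ratio[3] / ratio[1]), 1, tolerance = 1e-9)
  }
})

test_that("TMM component is exactly 1 under pure library-size scaling", {
  a <- c(10, 25, 40, 90, 3, 17, 60, 22, 35, 48, 11, 7, 13, 19, 23, 29, 31,
         37, 41, 43, 47, 53, 59, 61, 67)
  m <- expr_matrix(cbind(a, 3 * a), sprintf("g%d", seq_along(a)), c("A", "B"))
  sf <- size_factors_tmm(m)
  comp <- sf$params$tmm_component
  expect_equal(unname(comp), c(1, 1))
  # size factors reflect library size only
  expect_equal(unname(sf$factors[2] / sf$factors[1]), 3, tolerance = 1e-12)
})

test_that("TMM matches the brute-force trimming oracle", {
  set.seed(5)
  base <- rpois(40, 60) + 1
  b <- base
  b[1:2] <- b[1:2] * 40  # planted composition-biased genes
  m <- expr_matrix(cbind(base, b), sprintf("g%d", seq_along(base)), c("A", "B"))
  sf <- size_factors_tmm(m)
  N <- colSums(unclass(m))
  ref <- match(sf$params$reference, sample_ids(m))
  comp_oracle <- vapply(1:2, function(g) {
    tmm_oracle_component(unclass(m)[, g], unclass(m)[, ref], N[g], N[ref])
  }, numeric(1))
  raw <- comp_oracle * N
  expect_equal(unname(sf$factors), unname(raw / exp(mean(log(raw)))),
               tolerance = 1e-9)
})

test_that("TMM falls back to the untrimmed mean on tiny feature sets", {
  m <- random_counts(8, 2, seed = 2, zero_free = TRUE)
  w <- capture_warnings(size_factors_tmm(m))
  expect_true(any(grepl("untrimmed", w)))
})

test_that("upper-quartile factors use type-7 interpolation", {
  m <- expr_matrix(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4)),
                   sprintf("g%d", 1:4), c("A", "B"))
  # identical columns: all factors 1; raw Q75 of {1,2,3,4} = 3.25
  sf <- size_factors_upper_quartile(m)
  expect_equal(unname(sf$factors), c(1, 1))
  expect_equal(unname(stats::quantile(1:4, 0.75, type = 7)), 3.25)
  m0 <- expr_matrix(cbind(c(0, 0), c(1, 2)), c("g1", "g2"), c("A", "B"))
  expect_error(size_factors_upper_quartile(m0), "'A'")
})

test_that("spike-in factors equal median-of-ratios on the spike submatrix", {
  set.seed(9)
  bio <- matrix(rpois(40, 30), 20, 2)
  spikes <- rbind(c(4, 8), c(10, 20), c(6, 12))  # doubled in sample B
  m <- expr_matrix(rbind(bio, spikes),
                   c(sprintf("g%d", 1:20), sprintf("ERCC-%04d", 1:3)),
                   c("A", "B"))
  part <- detect_spike_ins(m)
  sf <- size_factors_spike_in(m, part)
  expect_equal(unname(sf$factors), c(1 / sqrt(2), sqrt(2)))
  sub <- expr_matrix(spikes, sprintf("ERCC-%04d", 1:3), c("A", "B"))
  expect_equal(sf$factors, size_factors_median_ratio(sub, 1)$factors)

  one_spike <- detect_spike_ins(m, prefix = "ERCC-0001")
  expect_error(size_factors_spike_in(m, one_spike), "at least 2")
})

test_that("CPM/TPM columns sum to one million; RPKM follows its formula", {
  m <- random_counts(40, 5, seed = 13)
  lengths <- stats::setNames(sample(200:5000, 40), feature_ids(m))
  cpm <- normalize_per_value(m, "cpm")$matrix
  tpm <- normalize_per_value(m, "tpm", lengths)$matrix
  expect_equal(unname(colSums(unclass(cpm))), rep(1e6, 5), tolerance = 1e-9)
  expect_equal(unname(colSums(unclass(tpm))), rep(1e6, 5), tolerance = 1e-9)

  single <- expr_matrix(matrix(10, 1, 1), "g1", "s1")
  rpkm <- normalize_per_value(single, "rpkm", c(g1 = 1000))$matrix
  expect_equal(unclass(rpkm)[1, 1], 1e9 * 10 / (10 * 1000))

  expect_error(normalize_per_value(m, "tpm", lengths[-1]),
               paste0("'", feature_ids(m)[1], "'"))
})

test_that("quantile normalization: worked example, fixed point, idempotence", {
  q <- expr_matrix(cbind(c(2, 4, 6), c(1, 5, 12)), sprintf("g%d", 1:3),
                   c("A", "B"))
  out <- unclass(quantile_normalize(q)$matrix)
  expect_equal(unname(out[, 1]), c(1.5, 4.5, 9))
  expect_equal(unname(out[, 2]), c(1.5, 4.5, 9))

  same <- expr_matrix(cbind(c(3, 1, 7), c(3, 1, 7)), sprintf("g%d", 1:3),
                      c("A", "B"))
  expect_equal(unclass(quantile_normalize(same)$matrix), unclass(same),
               ignore_attr = TRUE)

  set.seed(21)
  m <- expr_matrix(matrix(rlnorm(60), 20, 3), sprintf("g%d", 1:20),
                   c("A", "B", "C"))
  once <- quantile_normalize(m)$matrix
  sorted <- apply(unclass(once), 2, sort)
  expect_equal(sorted[, 1], sorted[, 2])
  expect_equal(sorted[, 1], sorted[, 3])
  twice <- quantile_normalize(once)$matrix
  expect_equal(unclass(twice), unclass(once), tolerance = 1e-12)
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(4)
  m <- expr_matrix(matrix(rlnorm(100), 25, 4), sprintf("g%d", 1:25),
                   sprintf("s%d", 1:4))
  mine <- unclass(quantile_normalize(m)$matrix)
  ref <- limma::normalizeQuantiles(unclass(m))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("applying size factors divides counts and handles the log option", {
  m <- expr_matrix(cbind(c(0, 7), c(2, 4)), c("g1", "g2"), c("A", "B"))
  ones <- size_factors(c(A = 1, B = 1), "manual")
  expect_equal(unclass(apply_size_factors(m, ones)$matrix), unclass(m),
               ignore_attr = TRUE)
  sf <- size_factors(c(A = 2, B = 0.5), "manual")
  res <- apply_size_factors(m, sf, log = TRUE)
  expect_equal(matrix_kind(res$matrix), "log_normalized")
  expect_equal(unclass(res$matrix)["g1", "A"], 0)        # log2(0/2 + 1)
  expect_equal(unclass(res$matrix)["g2", "A"], log2(4.5)) # log2(7/2 + 1)
  missing_sf <- size_factors(c(A = 1), "manual", rescale = FALSE)
  expect_error(apply_size_factors(m, missing_sf), "'B'")
})

test_that("all size-factor sets have geometric mean 1", {
  m <- random_counts(60, 5, seed = 3, zero_free = TRUE)
  for (method in c("median_ratio", "tmm", "upper_quartile")) {
    f <- normalize_counts(m, method)$size_factors$factors
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  }
})
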