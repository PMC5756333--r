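# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately written as direct transcriptions of the defining
# formulas (explicit sorting/enumeration), independent of the package's
# implementation paths.

random_counts <- function(n_features, n_samples, seed = 1, max_count = 100,
                          zero_free = FALSE) {
  set.seed(seed)
  lo <- if (zero_free) 1 else 0
  v <- matrix(sample(lo:max_count, n_features * n_samples, replace = TRUE),
              n_features, n_samples)
  expr_matrix(v, sprintf("g%03d", seq_len(n_features)),
              sprintf("s%02d", seq_len(n_samples)), kind = "counts")
}

worked_matrix_3x2 <- function() {
  expr_matrix(rbind(c(2, 8), c(4, 16), c(0, 5)),
              c("g1", "g2", "g3"), c("A", "B"))
}

frozen_clock <- function(stamp = "2020-01-01T00:00:00Z") function() stamp

# classic median-of-ratios on a zero-free matrix, rescaled to geometric mean 1
classic_median_ratio <- function(m) {
  v <- unclass(m)
  ref <- exp(rowMeans(log(v)))
  raw <- apply(v, 2, function(col) stats::median(col / ref))
  raw / exp(mean(log(raw)))
}

# brute-force TMM scaling component: explicit sort-based trim-set enumeration
tmm_oracle_component <- function(kg, kr, Ng, Nr, trim_m = 0.30, trim_a = 0.05) {
  ok <- kg > 0 & kr > 0
  kg <- kg[ok]; kr <- kr[ok]
  M <- log2((kg / Ng) / (kr / Nr))
  A <- 0.5 * log2((kg / Ng) * (kr / Nr))
  w <- 1 / ((Ng - kg) / (Ng * kg) + (Nr - kr) / (Nr * kr))
  n <- length(M)
  dm <- floor(n * trim_m); da <- floor(n * trim_a)
  keepM <- logical(n); keepM[order(M)[seq(dm + 1, n - dm)]] <- TRUE
  keepA <- logical(n); keepA[order(A)[seq(da + 1, n - da)]] <- TRUE
  keep <- keepM & keepA
  if (sum(keep) < 10) keep <- rep(TRUE, n)
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

# exhaustive two-sided Mann-Whitney p by enumerating all C(n, n_a) labelings
mwu_enumeration_p <- function(x, y) {
  all_vals <- c(x, y)
  n_a <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  combos <- utils::combn(length(all_vals), n_a)
  us <- apply(combos, 2, function(idx) u_of(all_vals[idx], all_vals[-idx]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# Benjamini-Hochberg step-up transcribed from its definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted_adj <- p[o] * n / seq_len(n)
  stepped <- rev(cummin(rev(sorted_adj)))
  out <- numeric(n)
  out[o] <- pmin(stepped, 1)
  out
}

worked_network <- function() {
  regulatory_network(
    data.frame(source = c("T", "T", "U"), target = c("a", "b", "a")),
    directed = TRUE)
}

worked_scores <- function() as_gene_scores(c(T = 1, a = 2, b = 3))

# small map with a normalize -> feature-filter chain plus a merge branch
fixture_map <- function(seed = 1) {
  sim <- simulate_counts(simulation_spec(n_features = 60, n_samples = 6,
                                         de_fraction = 0, dispersion = 0.05),
                         seed = seed)
  map <- create_map(sim$matrix, "raw", clock = frozen_clock())
  set_context(map, design = sim$design)
  n_filt <- dm_filter_features(map, map$root_id,
                               feature_criteria(min_count = 1, min_samples = 2))
  n_norm <- dm_normalize(map, n_filt, "median_ratio")
  n_sub <- dm_subset(map, map$root_id,
                     sample_ids = sample_ids(sim$matrix)[1:3],
                     label = "first half")
  n_sub2 <- dm_subset(map, map$root_id,
                      sample_ids = sample_ids(sim$matrix)[4:6],
                      label = "second half")
  n_merge <- dm_merge(map, c(n_sub, n_sub2), axis = "samples")
  list(map = map, nodes = list(norm = n_norm, filt = n_filt, sub = n_sub,
                               sub2 = n_sub2, merge = n_merge))
}
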