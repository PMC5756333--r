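#' Size factor container
#'
#' All size-factor estimators in the package return this object. Factors are
#' rescaled so their geometric mean is 1, which makes methods directly
#' comparable; normalized values are counts divided by the factor.
#'
#' @param factors Named positive numeric vector (names = sample IDs).
#' @param method Estimator name.
#' @param params List of estimator parameters.
#' @param rescale Rescale to geometric mean 1 (default TRUE).
#' @return A `size_factors` object.
#' @export
size_factors <- function(factors, method, params = list(), rescale = TRUE) {
  if (anyNA(factors) || any(!is.finite(factors)) || any(factors <= 0))
    stop("size factors must be positive and finite", call. = FALSE)
  if (is.null(names(factors)) || any(!nzchar(names(factors))))
    stop("size factors must be named by sample", call. = FALSE)
  if (rescale) factors <- factors / exp(mean(log(factors)))
  structure(list(factors = factors, method = method, params = params),
            class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat("<size_factors> method =", x$method, "\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.size_factors <- function(x, ...) {
  tibble::tibble(sample_id = names(x$factors), size_factor = unname(x$factors))
}

#' Export size factors as a two-column TSV
#'
#' @param sf A `size_factors` object.
#' @param path Output path.
#' @export
write_size_factors <- function(sf, path) {
  writeLines(c("sample\tfactor",
               paste(names(sf$factors), fmt_num(sf$factors), sep = "\t")), path)
  invisible(path)
}

geomean_positive <- function(x) {
  pos <- x[x > 0]
  exp(mean(log(pos)))
}

#' Median-of-ratios size factors with a tunable inclusion criterion
#'
#' The classic median-of-ratios estimator requires every feature used for the
#' reference to be detected in every sample, which discards almost everything
#' in sparse single-cell matrices. This variant makes the inclusion criterion
#' a parameter: a feature enters the reference if it is detected (count > 0)
#' in at least `ceiling(min_detect_frac * n_samples)` samples. The
#' per-feature reference is the geometric mean of its positive counts, and
#' each sample's raw factor is the median of its positive count-to-reference
#' ratios over included features. With `min_detect_frac = 1` on a zero-free
#' matrix this is exactly the classic estimator.
#'
#' @param matrix Count `expr_matrix` with at least two samples.
#' @param min_detect_frac Fraction in (0, 1]; inclusion criterion.
#' @return A `size_factors` object (geometric mean 1).
#' @export
size_factors_median_ratio <- function(matrix, min_detect_frac = 1) {
  check_counts(matrix, min_samples = 2)
  if (min_detect_frac <= 0 || min_detect_frac > 1)
    stop("min_detect_frac must be in (0, 1]", call. = FALSE)
  v <- unclass(matrix)
  m <- ncol(v)
  n_pos <- rowSums(v > 0)
  keep <- n_pos >= ceiling(min_detect_frac * m)
  if (!any(keep))
    stop("no feature is detected in enough samples; lower min_detect_frac",
         call. = FALSE)
  sub <- v[keep, , drop = FALSE]
  ref <- apply(sub, 1, geomean_positive)
  raw <- vapply(seq_len(m), function(j) {
    k <- sub[, j]
    ok <- k > 0
    if (!any(ok))
      stop("sample '", sample_ids(matrix)[j],
           "' has no positive count among included features", call. = FALSE)
    stats::median(k[ok] / ref[ok])
  }, numeric(1))
  names(raw) <- sample_ids(matrix)
  size_factors(raw, "median_ratio", list(min_detect_frac = min_detect_frac))
}

check_counts <- function(matrix, min_samples = 1) {
  if (!inherits(matrix, "expr_matrix") || matrix_kind(matrix) != "counts")
    stop("a count matrix (kind = counts) is required", call. = FALSE)
  if (ncol(matrix) < min_samples)
    stop("at least ", min_samples, " samples required", call. = FALSE)
  invisible(matrix)
}

#' Trimmed mean of M-values (TMM) size factors
#'
#' Composition-robust scaling. The reference sample is the one whose upper
#' quartile of positive counts is closest to the mean upper quartile. For
#' each sample, log2 expression ratios (M) and average log intensities (A)
#' against the reference are computed over features positive in both; the
#' top and bottom `trim_m` fraction by M and `trim_a` fraction by A are
#' dropped, and the scaling component is two to the power of the weighted
#' mean of the remaining M values, with inverse approximate-variance weights.
#' The final size factor multiplies this component by the library size and is
#' rescaled to geometric mean 1. The per-sample scaling components are kept
#' in `params$tmm_component`.
#'
#' @param matrix Count `expr_matrix`, at least two samples.
#' @param trim_m Two-sided trim fraction on M values (default 0.30).
#' @param trim_a Two-sided trim fraction on A values (default 0.05).
#' @return A `size_factors` object.
#' @export
size_factors_tmm <- function(matrix, trim_m = 0.30, trim_a = 0.05) {
  check_counts(matrix, min_samples = 2)
  v <- unclass(matrix)
  N <- colSums(v)
  if (any(N <= 0)) stop("every sample needs a positive total count", call. = FALSE)
  uq <- apply(v, 2, function(x) stats::quantile(x[x > 0], 0.75, type = 7))
  ref <- which.min(abs(uq - mean(uq)))
  comp <- vapply(seq_len(ncol(v)), function(g) {
    tmm_component(v[, g], v[, ref], N[g], N[ref], trim_m, trim_a)
  }, numeric(1))
  raw <- comp * N
  names(raw) <- sample_ids(matrix)
  size_factors(raw, "tmm",
               list(trim_m = trim_m, trim_a = trim_a,
                    reference = sample_ids(matrix)[ref],
                    tmm_component = stats::setNames(comp, sample_ids(matrix))))
}

tmm_component <- function(kg, kr, Ng, Nr, trim_m, trim_a) {
  ok <- kg > 0 & kr > 0
  kg <- kg[ok]; kr <- kr[ok]
  if (!length(kg)) return(1)
  M <- log2((kg / Ng) / (kr / Nr))
  A <- 0.5 * log2((kg / Ng) * (kr / Nr))
  w <- 1 / ((Ng - kg) / (Ng * kg) + (Nr - kr) / (Nr * kr))
  n <- length(M)
  dm <- floor(n * trim_m)
  da <- floor(n * trim_a)
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM > dm & rM <= n - dm & rA > da & rA <= n - da
  if (sum(keep) < 10) {
    warning("fewer than 10 features remain after trimming; ",
            "using the untrimmed weighted mean", call. = FALSE)
    keep <- rep(TRUE, n)
  }
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

#' Upper-quartile size factors
#'
#' Raw factor = 75th percentile (linear interpolation) of each sample's
#' positive counts, rescaled to geometric mean 1.
#'
#' @param matrix Count `expr_matrix`.
#' @return A `size_factors` object.
#' @export
size_factors_upper_quartile <- function(matrix) {
  check_counts(matrix, min_samples = 1)
  v <- unclass(matrix)
  raw <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    pos <- x[x > 0]
    if (!length(pos))
      stop("sample '", sample_ids(matrix)[j], "' has no positive count",
           call. = FALSE)
    unname(stats::quantile(pos, 0.75, type = 7))
  }, numeric(1))
  names(raw) <- sample_ids(matrix)
  size_factors(raw, "upper_quartile")
}

#' Spike-in based size factors
#'
#' Median-of-ratios (inclusion fraction 1) computed on the spike-in rows
#' only; the resulting factors are meant to be applied to the full matrix.
#'
#' @param matrix Count `expr_matrix`.
#' @param partition A spike partition from [detect_spike_ins()].
#' @return A `size_factors` object.
#' @export
size_factors_spike_in <- function(matrix, partition) {
  if (length(partition$spike_feature_ids) < 2)
    stop("at least 2 spike-in features are required", call. = FALSE)
  sub <- subset_matrix(matrix, features = partition$spike_feature_ids)
  sf <- size_factors_median_ratio(sub, min_detect_frac = 1)
  size_factors(sf$factors, "spike_in",
               list(n_spikes = length(partition$spike_feature_ids)),
               rescale = FALSE)
}

#' Per-value normalization: CPM, RPKM, TPM
#'
#' CPM scales each count to counts per million of its library; RPKM
#' additionally divides by feature length in kilobases; TPM first
#' length-normalizes and then scales each column to one million, so every
#' TPM (and CPM) column sums to 1e6.
#'
#' @param matrix Count `expr_matrix` with positive column sums.
#' @param mode `"cpm"`, `"rpkm"` or `"tpm"`.
#' @param lengths Named vector of feature lengths in bases (required for
#'   rpkm/tpm; must cover every feature).
#' @return A `normalization_result` (no size factors).
#' @export
normalize_per_value <- function(matrix, mode = c("cpm", "rpkm", "tpm"),
                                lengths = NULL) {
  mode <- match.arg(mode)
  check_counts(matrix, min_samples = 1)
  v <- unclass(matrix)
  N <- colSums(v)
  if (any(N <= 0)) stop("every column sum must be positive", call. = FALSE)
  if (mode != "cpm") {
    if (is.null(lengths)) stop("mode '", mode, "' requires gene lengths", call. = FALSE)
    check_gene_lengths(lengths)
    missing <- setdiff(feature_ids(matrix), names(lengths))
    if (length(missing))
      stop("no length for feature '", missing[[1]], "'", call. = FALSE)
    L <- lengths[feature_ids(matrix)]
  }
  out <- switch(mode,
    cpm = sweep(v, 2, N, "/") * 1e6,
    rpkm = sweep(v / L, 2, N, "/") * 1e9,
    tpm = {
      x <- v / L
      sweep(x, 2, colSums(x), "/") * 1e6
    })
  res_matrix <- expr_matrix(out, feature_ids(matrix), sample_ids(matrix),
                            kind = "normalized")
  normalization_result(res_matrix, NULL,
                       operation("normalize", list(method = mode)))
}

#' Quantile normalization
#'
#' Classic rank-mean procedure: each column is sorted, values are averaged
#' across columns at each rank, and each column's values are replaced by the
#' rank-mean at their original rank. Tied values within a column receive the
#' mean of the rank-means their positions span.
#'
#' @param matrix An `expr_matrix` with at least two samples.
#' @return A `normalization_result` (no size factors).
#' @export
quantile_normalize <- function(matrix) {
  if (ncol(matrix) < 2) stop("at least 2 samples required", call. = FALSE)
  v <- unclass(matrix)
  rank_means <- rowMeans(base::matrix(apply(v, 2, sort), nrow = nrow(v)))
  out <- apply(v, 2, function(x) {
    assigned <- numeric(length(x))
    assigned[order(x)] <- rank_means
    stats::ave(assigned, match(x, x), FUN = mean)
  })
  out <- base::matrix(out, nrow = nrow(v))
  dimnames(out) <- dimnames(v)
  res <- expr_matrix(out, feature_ids(matrix), sample_ids(matrix),
                     kind = "normalized")
  normalization_result(res, NULL, operation("normalize", list(method = "quantile")))
}

#' Divide counts by size factors (optionally log2)
#'
#' @param matrix Count `expr_matrix`.
#' @param sf A `size_factors` object covering every sample.
#' @param log If TRUE, return `log2(count / factor + pseudocount)`.
#' @param pseudocount Added before the log (default 1).
#' @return A `normalization_result` carrying the size factors.
#' @export
apply_size_factors <- function(matrix, sf, log = FALSE, pseudocount = 1) {
  missing <- setdiff(sample_ids(matrix), names(sf$factors))
  if (length(missing))
    stop("no size factor for sample '", missing[[1]], "'", call. = FALSE)
  v <- sweep(unclass(matrix), 2, sf$factors[sample_ids(matrix)], "/")
  kind <- "normalized"
  if (log) {
    v <- log2(v + pseudocount)
    kind <- "log_normalized"
  }
  res <- expr_matrix(v, feature_ids(matrix), sample_ids(matrix), kind = kind)
  normalization_result(res, sf,
                       operation("normalize",
                                 c(list(method = sf$method), sf$params[
                                   setdiff(names(sf$params), "tmm_component")],
                                   list(log = log, pseudocount = pseudocount))))
}

normalization_result <- function(matrix, sf, op) {
  structure(list(matrix = matrix, size_factors = sf, op = op),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("<normalization_result> method =", x$op$params$method, "\n")
  print(x$matrix)
  invisible(x)
}

#' One-call normalization front end
#'
#' Computes size factors where the method has them and returns the
#' normalized matrix; this is also the entry point the data-map replay
#' machinery uses, so its parameters fully determine its output.
#'
#' @param matrix Count `expr_matrix`.
#' @param method One of `"median_ratio"`, `"tmm"`, `"upper_quartile"`,
#'   `"spike_in"`, `"cpm"`, `"rpkm"`, `"tpm"`, `"quantile"`.
#' @param min_detect_frac Inclusion fraction for `median_ratio`.
#' @param trim_m,trim_a Trim fractions for `tmm`.
#' @param spike_prefix Spike-in ID prefix for `spike_in`.
#' @param lengths Feature lengths for `rpkm`/`tpm`.
#' @param log,pseudocount Log-transform options for factor-based methods.
#' @return A `normalization_result`.
#' @export
normalize_counts <- function(matrix,
                             method = c("median_ratio", "tmm", "upper_quartile",
                                        "spike_in", "cpm", "rpkm", "tpm",
                                        "quantile"),
                             min_detect_frac = 1, trim_m = 0.30, trim_a = 0.05,
                             spike_prefix = "ERCC-", lengths = NULL,
                             log = FALSE, pseudocount = 1) {
  method <- match.arg(method)
  if (method %in% c("cpm", "rpkm", "tpm")) {
    return(normalize_per_value(matrix, method, lengths))
  }
  if (method == "quantile") return(quantile_normalize(matrix))
  sf <- switch(method,
    median_ratio = size_factors_median_ratio(matrix, min_detect_frac),
    tmm = size_factors_tmm(matrix, trim_m, trim_a),
    upper_quartile = size_factors_upper_quartile(matrix),
    spike_in = size_factors_spike_in(matrix, detect_spike_ins(matrix, spike_prefix)))
  res <- apply_size_factors(matrix, sf, log = log, pseudocount = pseudocount)
  extra <- switch(method,
    median_ratio = list(min_detect_frac = min_detect_frac),
    tmm = list(trim_m = trim_m, trim_a = trim_a),
    spike_in = list(spike_prefix = spike_prefix),
    list())
  res$op <- operation("normalize",
                      c(list(method = method), extra,
                        list(log = log, pseudocount = pseudocount)))
  res
}
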