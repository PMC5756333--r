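#' Per-sample quality-control statistics
#'
#' Total counts, number of detected features (positive entries), dropout rate
#' (fraction of zero entries) and, if size factors are supplied, the
#' estimated size factor — the summaries used to spot outlying samples before
#' filtering.
#'
#' @param matrix Count `expr_matrix`.
#' @param sf Optional `size_factors` object.
#' @return A tibble with one row per sample.
#' @export
sample_qc_stats <- function(matrix, sf = NULL) {
  check_counts(matrix)
  v <- unclass(matrix)
  n_feat <- nrow(v)
  out <- tibble::tibble(
    sample_id = sample_ids(matrix),
    total_counts = unname(colSums(v)),
    detected_features = unname(colSums(v > 0)),
    dropout_rate = if (n_feat) unname(colSums(v == 0) / n_feat)
                   else rep(NA_real_, ncol(v))
  )
  if (!is.null(sf)) out$size_factor <- unname(sf$factors[out$sample_id])
  out
}

#' Feature filter criteria
#'
#' Inactive criteria are `NULL`. A feature is removed if it fails any active
#' expression criterion; `keep_list` overrides the expression criteria and
#' `drop_list` removes its members unconditionally. List entries that name
#' unknown features are ignored with a warning.
#'
#' @param min_mean_expr Keep features whose mean value is at least this.
#' @param min_count,min_samples Keep features with at least `min_count` in at
#'   least `min_samples` samples.
#' @param keep_list,drop_list Explicit feature ID lists.
#' @return A `feature_criteria` list.
#' @export
feature_criteria <- function(min_mean_expr = NULL, min_count = NULL,
                             min_samples = 1, keep_list = NULL,
                             drop_list = NULL) {
  structure(list(min_mean_expr = min_mean_expr, min_count = min_count,
                 min_samples = min_samples, keep_list = keep_list,
                 drop_list = drop_list),
            class = "feature_criteria")
}

#' Sample filter criteria
#'
#' Ranges are length-2 numeric vectors `(lo, hi)`, inclusive. A sample is
#' removed if any of its QC statistics falls outside an active range or its
#' dropout rate exceeds `max_dropout`; `keep_list` overrides the statistical
#' criteria, `drop_list` removes unconditionally.
#'
#' @param total_range Range on total counts.
#' @param detected_range Range on detected features.
#' @param max_dropout Maximum dropout rate.
#' @param size_factor_range Range on the size factor.
#' @param keep_list,drop_list Explicit sample ID lists.
#' @return A `sample_criteria` list.
#' @export
sample_criteria <- function(total_range = NULL, detected_range = NULL,
                            max_dropout = NULL, size_factor_range = NULL,
                            keep_list = NULL, drop_list = NULL) {
  for (r in list(total_range, detected_range, size_factor_range)) {
    if (!is.null(r) && (length(r) != 2 || r[1] > r[2]))
      stop("ranges must be (lo, hi) with lo <= hi", call. = FALSE)
  }
  structure(list(total_range = total_range, detected_range = detected_range,
                 max_dropout = max_dropout,
                 size_factor_range = size_factor_range,
                 keep_list = keep_list, drop_list = drop_list),
            class = "sample_criteria")
}

check_known_ids <- function(list_ids, known, what) {
  unknown <- setdiff(list_ids, known)
  if (length(unknown)) {
    warning("ignoring ", length(unknown), " unknown ", what, " ID(s): '",
            unknown[[1]], "'", if (length(unknown) > 1) ", ..." else "",
            call. = FALSE)
  }
  intersect(list_ids, known)
}

#' Filter features by expression and list criteria
#'
#' @param matrix An `expr_matrix`.
#' @param criteria A [feature_criteria()] object.
#' @return A list with `matrix` (survivors, samples unchanged) and
#'   `removed_ids`.
#' @export
filter_features <- function(matrix, criteria) {
  stopifnot(inherits(criteria, "feature_criteria"))
  v <- unclass(matrix)
  ids <- feature_ids(matrix)
  keep <- rep(TRUE, length(ids))
  if (!is.null(criteria$min_mean_expr))
    keep <- keep & rowMeans(v) >= criteria$min_mean_expr
  if (!is.null(criteria$min_count))
    keep <- keep & rowSums(v >= criteria$min_count) >= criteria$min_samples
  if (!is.null(criteria$keep_list)) {
    kl <- check_known_ids(criteria$keep_list, ids, "feature")
    keep[ids %in% kl] <- TRUE
  }
  if (!is.null(criteria$drop_list)) {
    dl <- check_known_ids(criteria$drop_list, ids, "feature")
    keep[ids %in% dl] <- FALSE
  }
  if (!any(keep)) stop("all features removed", call. = FALSE)
  list(matrix = subset_matrix(matrix, features = ids[keep]),
       removed_ids = ids[!keep])
}

#' Filter samples by QC statistics and list criteria
#'
#' @param matrix An `expr_matrix`.
#' @param criteria A [sample_criteria()] object.
#' @param qc QC tibble from [sample_qc_stats()] computed on the same matrix
#'   (required when any statistical criterion is active).
#' @return A list with `matrix` (features unchanged) and `removed_ids`.
#' @export
filter_samples <- function(matrix, criteria, qc = NULL) {
  stopifnot(inherits(criteria, "sample_criteria"))
  ids <- sample_ids(matrix)
  needs_qc <- !is.null(criteria$total_range) || !is.null(criteria$detected_range) ||
    !is.null(criteria$max_dropout) || !is.null(criteria$size_factor_range)
  if (needs_qc) {
    if (is.null(qc)) stop("statistical sample criteria require QC stats", call. = FALSE)
    if (!setequal(qc$sample_id, ids) || nrow(qc) != length(ids))
      stop("QC stats must cover exactly the matrix samples", call. = FALSE)
    qc <- qc[match(ids, qc$sample_id), ]
  }
  keep <- rep(TRUE, length(ids))
  in_range <- function(x, r) x >= r[1] & x <= r[2]
  if (!is.null(criteria$total_range))
    keep <- keep & in_range(qc$total_counts, criteria$total_range)
  if (!is.null(criteria$detected_range))
    keep <- keep & in_range(qc$detected_features, criteria$detected_range)
  if (!is.null(criteria$max_dropout))
    keep <- keep & qc$dropout_rate <= criteria$max_dropout
  if (!is.null(criteria$size_factor_range)) {
    if (is.null(qc$size_factor))
      stop("size_factor_range requires QC stats with a size_factor column",
           call. = FALSE)
    keep <- keep & in_range(qc$size_factor, criteria$size_factor_range)
  }
  if (!is.null(criteria$keep_list)) {
    kl <- check_known_ids(criteria$keep_list, ids, "sample")
    keep[ids %in% kl] <- TRUE
  }
  if (!is.null(criteria$drop_list)) {
    dl <- check_known_ids(criteria$drop_list, ids, "sample")
    keep[ids %in% dl] <- FALSE
  }
  if (!any(keep)) stop("all samples removed", call. = FALSE)
  list(matrix = subset_matrix(matrix, samples = ids[keep]),
       removed_ids = ids[!keep])
}

#' Rank-frequency table for one sample
#'
#' Positive counts sorted descending; rank 1..n over the positive features,
#' frequency = count / sample total. Ties keep descending order and receive
#' sequential ranks.
#'
#' @param matrix Count `expr_matrix`.
#' @param sample_id Sample to summarize.
#' @return A tibble `(feature_id, rank, frequency)` whose frequencies sum
#'   to 1.
#' @export
rank_frequency <- function(matrix, sample_id) {
  if (!sample_id %in% sample_ids(matrix))
    stop("unknown sample ID: '", sample_id, "'", call. = FALSE)
  x <- unclass(matrix)[, sample_id]
  total <- sum(x)
  if (total <= 0) stop("sample '", sample_id, "' has no positive count", call. = FALSE)
  pos <- x[x > 0]
  ord <- order(pos, decreasing = TRUE)
  tibble::tibble(feature_id = names(pos)[ord],
                 rank = seq_along(ord),
                 frequency = unname(pos[ord]) / total)
}

#' Per-feature mean, standard deviation and coefficient of variation
#'
#' Intended for normalized or log-normalized values. The standard deviation
#' uses the n-1 denominator; the coefficient of variation is `NA` where the
#' mean is zero.
#'
#' @param matrix An `expr_matrix` with at least two samples.
#' @return A tibble `(feature_id, mean, sd, cv)` in matrix row order.
#' @export
mean_variability <- function(matrix) {
  if (ncol(matrix) < 2) stop("at least 2 samples required", call. = FALSE)
  v <- unclass(matrix)
  mu <- rowMeans(v)
  sd <- apply(v, 1, stats::sd)
  tibble::tibble(feature_id = feature_ids(matrix), mean = unname(mu),
                 sd = unname(sd),
                 cv = ifelse(mu == 0, NA_real_, sd / mu))
}

#' Find features with expression patterns similar to a target
#'
#' Correlates every other feature with the target across samples and returns
#' the strongest associations. Constant features cannot be correlated and are
#' skipped with a warning.
#'
#' @param matrix Normalized `expr_matrix`.
#' @param target Feature ID to query.
#' @param method `"pearson"` or `"spearman"`.
#' @param top_n Number of features to return (default all).
#' @return A tibble `(feature_id, correlation)` sorted descending.
#' @export
feature_query <- function(matrix, target, method = c("pearson", "spearman"),
                          top_n = Inf) {
  method <- match.arg(method)
  ids <- feature_ids(matrix)
  if (!target %in% ids) stop("unknown feature ID: '", target, "'", call. = FALSE)
  v <- unclass(matrix)
  y <- v[target, ]
  if (stats::sd(y) == 0) stop("target feature '", target, "' is constant", call. = FALSE)
  others <- setdiff(ids, target)
  const <- others[apply(v[others, , drop = FALSE], 1, stats::sd) == 0]
  if (length(const))
    warning("skipping ", length(const), " constant feature(s)", call. = FALSE)
  use <- setdiff(others, const)
  r <- as.numeric(stats::cor(t(v[use, , drop = FALSE]), y, method = method))
  out <- tibble::tibble(feature_id = use, correlation = r)
  out <- dplyr::arrange(out, dplyr::desc(.data$correlation))
  utils::head(out, top_n)
}
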