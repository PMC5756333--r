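#' Two-group assignment
#'
#' @param groups Either a named character vector (names = sample IDs, values
#'   = group labels) or a data frame with `sample_id` and `group` columns.
#'   Exactly two labels must be in use and each group needs at least two
#'   samples.
#' @return A named character vector.
#' @export
as_group_assignment <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups)))
      stop("group data frame needs 'sample_id' and 'group' columns", call. = FALSE)
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample_id))
  }
  if (is.null(names(groups)))
    stop("groups must be named by sample ID", call. = FALSE)
  labels <- sort(unique(groups))
  if (length(labels) != 2)
    stop("exactly two group labels are required (found ", length(labels), ")",
         call. = FALSE)
  counts <- table(groups)
  if (any(counts < 2))
    stop("each group needs at least 2 samples; group '",
         names(counts)[which.min(counts)], "' has ", min(counts), call. = FALSE)
  groups
}

#' Per-feature Mann-Whitney U differential expression
#'
#' For every feature a two-sided Mann-Whitney (Wilcoxon rank-sum) test
#' between the two groups of normalized values. The exact null distribution
#' is used when the larger group has at most 8 samples and the feature's
#' values are tie-free; otherwise the normal approximation with tie and
#' continuity correction. The reported U statistic counts pairs in favour of
#' the first (alphabetically) group; features whose values are identical
#' across all samples carry no information and get p = 1. P-values are
#' adjusted across all tested features with the Benjamini-Hochberg step-up,
#' and the fold change is `log2((mean_a + pseudocount)/(mean_b + pseudocount))`.
#'
#' @param matrix Normalized `expr_matrix` (rank tests are invariant to
#'   monotone transforms, so counts or log values give the same p-values).
#' @param groups A two-group assignment (see [as_group_assignment()]).
#' @param pseudocount Stabilizer for the fold change (default 1).
#' @return A `de_result`; use [tidy()] for the per-feature table and
#'   [glance()] for the metadata.
#' @export
mwu_de <- function(matrix, groups, pseudocount = 1) {
  groups <- as_group_assignment(groups)
  missing <- setdiff(names(groups), sample_ids(matrix))
  if (length(missing))
    stop("sample '", missing[[1]], "' is not in the matrix", call. = FALSE)
  labels <- sort(unique(groups))
  a_ids <- names(groups)[groups == labels[1]]
  b_ids <- names(groups)[groups == labels[2]]
  v <- unclass(matrix)
  n_a <- length(a_ids); n_b <- length(b_ids)
  res <- lapply(seq_len(nrow(v)), function(i) {
    mwu_single(v[i, a_ids], v[i, b_ids])
  })
  tab <- tibble::tibble(
    feature_id = feature_ids(matrix),
    u_statistic = vapply(res, `[[`, numeric(1), "u"),
    p_value = vapply(res, `[[`, numeric(1), "p"),
    mean_a = unname(rowMeans(v[, a_ids, drop = FALSE])),
    mean_b = unname(rowMeans(v[, b_ids, drop = FALSE])),
    method = vapply(res, `[[`, character(1), "method")
  )
  tab$p_adjusted <- bh_adjust(tab$p_value)
  tab$log2_fc <- log2((tab$mean_a + pseudocount) / (tab$mean_b + pseudocount))
  tab <- tab[, c("feature_id", "u_statistic", "p_value", "p_adjusted",
                 "log2_fc", "mean_a", "mean_b", "method")]
  structure(list(table = tab,
                 group_a = labels[1], group_b = labels[2],
                 n_a = n_a, n_b = n_b, pseudocount = pseudocount),
            class = "de_result")
}

mwu_single <- function(x, y) {
  n_a <- length(x); n_b <- length(y)
  if (length(unique(c(x, y))) == 1L) {
    return(list(u = n_a * n_b / 2, p = 1, method = "degenerate"))
  }
  tie_free <- !anyDuplicated(c(x, y))
  exact <- tie_free && max(n_a, n_b) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(u = unname(wt$statistic), p = min(wt$p.value, 1),
       method = if (exact) "exact" else "normal")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> Mann-Whitney U, ", x$group_a, " (n=", x$n_a, ") vs ",
      x$group_b, " (n=", x$n_b, "), ", nrow(x$table), " features\n", sep = "")
  print(utils::head(dplyr::arrange(x$table, .data$p_adjusted), 6))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.de_result <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.de_result <- function(x, ...) {
  tibble::tibble(group_a = x$group_a, group_b = x$group_b,
                 n_a = x$n_a, n_b = x$n_b, n_features = nrow(x$table),
                 pseudocount = x$pseudocount,
                 n_exact = sum(x$table$method == "exact"))
}

#' Write a DE table as TSV
#'
#' @param result A `de_result`.
#' @param path Output path.
#' @export
write_de_table <- function(result, path) {
  utils::write.table(as.data.frame(tidy(result)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Markdown report of significant features
#'
#' Lists features with adjusted p at or below `alpha`, sorted by adjusted p
#' then absolute fold change, truncated to `top_n`, with the test parameters
#' embedded.
#'
#' @param result A `de_result`.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param top_n Maximum rows (default 100).
#' @return A `cf_report` object (markdown body + tables).
#' @export
de_report <- function(result, alpha = 0.05, top_n = 100) {
  tab <- tidy(result)
  hits <- dplyr::filter(tab, .data$p_adjusted <= alpha)
  hits <- dplyr::arrange(hits, .data$p_adjusted, dplyr::desc(abs(.data$log2_fc)))
  hits <- utils::head(hits, top_n)
  params <- list(alpha = alpha, top_n = top_n,
                 group_a = result$group_a, group_b = result$group_b,
                 n_a = result$n_a, n_b = result$n_b,
                 pseudocount = result$pseudocount,
                 adjustment = "BH")
  body <- c(
    "## Differential expression (Mann-Whitney U)",
    "",
    paste0("Parameters: ", jsonlite::toJSON(params, auto_unbox = TRUE)),
    "",
    if (nrow(hits) == 0) {
      paste0("No features significant at adjusted p <= ", alpha, " (zero hits).")
    } else {
      c(paste0(nrow(hits), " significant feature(s) at adjusted p <= ", alpha, ":"),
        "",
        md_table(hits))
    })
  new_report(recipe_id = NA_character_, produced_on = NA_character_,
             body = paste(body, collapse = "\n"),
             tables = list(significant = hits))
}

md_table <- function(df, digits = 4) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
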