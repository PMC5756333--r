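#' Construct an expression matrix
#'
#' The core container of the package: a feature-by-sample numeric matrix with
#' unique feature and sample identifiers and a `kind` flag distinguishing raw
#' counts from normalized and log-normalized values. Raw counts must be
#' non-negative and finite but need not be integer, so estimated counts from
#' quantifiers that produce fractional values are accepted.
#'
#' @param values Numeric matrix, rows = features, columns = samples.
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to `rownames(values)`).
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `colnames(values)`).
#' @param kind One of `"counts"`, `"normalized"`, `"log_normalized"`.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values,
                        feature_ids = rownames(values),
                        sample_ids = colnames(values),
                        kind = c("counts", "normalized", "log_normalized")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- character(0)
  if (is.null(sample_ids)) sample_ids <- character(0)
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("feature_ids length (", length(feature_ids),
         ") does not match row count (", nrow(values), ")", call. = FALSE)
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length (", length(sample_ids),
         ") does not match column count (", ncol(values), ")", call. = FALSE)
  check_unique_ids(feature_ids, "feature")
  check_unique_ids(sample_ids, "sample")
  if (kind == "counts" && length(values)) {
    if (any(!is.finite(values)))
      stop("count matrix contains non-finite values", call. = FALSE)
    if (any(values < 0))
      stop("count matrix contains negative values", call. = FALSE)
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, kind = kind, class = c("expr_matrix", "matrix", "array"))
}

check_unique_ids <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate ", what, " ID: '", dup[[1]], "'", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x), " features x ", ncol(x), " samples, kind = ",
      matrix_kind(x), "\n", sep = "")
  if (nrow(x) && ncol(x)) {
    show <- unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE]
    print(show)
    if (nrow(x) > 5 || ncol(x) > 5) cat("...\n")
  }
  invisible(x)
}

#' Matrix accessors
#'
#' @param x An `expr_matrix`.
#' @return `feature_ids()` / `sample_ids()` return character vectors;
#'   `matrix_kind()` returns the kind flag.
#' @export
feature_ids <- function(x) rownames(x) %||% character(0)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x) %||% character(0)

#' @rdname feature_ids
#' @export
matrix_kind <- function(x) attr(x, "kind") %||% "counts"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Ignored.
#' @return A tibble with columns `feature_id`, `sample_id`, `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.expr_matrix <- function(x, ...) {
  if (!nrow(x) || !ncol(x)) {
    return(tibble::tibble(feature_id = character(0), sample_id = character(0),
                          value = numeric(0)))
  }
  tibble::tibble(
    feature_id = rep(feature_ids(x), times = ncol(x)),
    sample_id = rep(sample_ids(x), each = nrow(x)),
    value = as.numeric(unclass(x))
  )
}

subset_matrix <- function(m, features = NULL, samples = NULL) {
  f <- features %||% feature_ids(m)
  s <- samples %||% sample_ids(m)
  missing_f <- setdiff(f, feature_ids(m))
  if (length(missing_f))
    stop("unknown feature ID: '", missing_f[[1]], "'", call. = FALSE)
  missing_s <- setdiff(s, sample_ids(m))
  if (length(missing_s))
    stop("unknown sample ID: '", missing_s[[1]], "'", call. = FALSE)
  expr_matrix(unclass(m)[f, s, drop = FALSE], f, s, kind = matrix_kind(m))
}

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

#' Read a count matrix from disk
#'
#' Supports two layouts: a delimited table (first column feature IDs, header
#' row sample IDs; delimiter inferred from the extension, `.csv` = comma,
#' anything else = tab, overridable via `delim`) and the 10x-style
#' MatrixMarket triplet (`matrix.mtx` plus one feature ID and one barcode per
#' line in companion files; 1-based coordinates, features = rows, barcodes =
#' columns).
#'
#' @param path Path to the matrix file.
#' @param format `"delimited"` or `"mtx_triplet"`.
#' @param delim Optional delimiter override for the delimited format.
#' @param features_path,barcodes_path Companion files for `mtx_triplet`.
#' @return An `expr_matrix` of kind `"counts"` with file order preserved.
#' @export
read_counts <- function(path, format = c("delimited", "mtx_triplet"),
                        delim = NULL, features_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "delimited") {
    read_counts_delimited(path, infer_delim(path, delim))
  } else {
    if (is.null(features_path) || is.null(barcodes_path))
      stop("mtx_triplet format requires features_path and barcodes_path", call. = FALSE)
    read_counts_mtx(path, features_path, barcodes_path)
  }
}

read_counts_delimited <- function(path, delim) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  cells <- strsplit(lines, delim, fixed = TRUE)
  header <- cells[[1]]
  n_col <- length(header)
  samples <- if (n_col > 1) header[-1] else character(0)
  body <- cells[-1]
  widths <- lengths(body)
  bad <- which(widths != n_col)
  if (length(bad))
    stop("ragged row at line ", bad[[1]] + 1L, ": expected ", n_col,
         " fields, found ", widths[bad[[1]]], call. = FALSE)
  features <- vapply(body, `[[`, character(1), 1L)
  vals <- if (length(body)) {
    raw <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
    num <- suppressWarnings(as.numeric(raw))
    if (anyNA(num)) {
      bad_cell <- raw[which(is.na(num))[1]]
      stop("non-numeric value '", bad_cell, "' in count matrix", call. = FALSE)
    }
    matrix(num, nrow = length(body), ncol = n_col - 1L, byrow = TRUE)
  } else {
    matrix(numeric(0), nrow = 0, ncol = max(n_col - 1L, 0L))
  }
  expr_matrix(vals, features, samples, kind = "counts")
}

read_counts_mtx <- function(path, features_path, barcodes_path) {
  for (p in c(features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  sp <- Matrix::readMM(path)
  features <- read_id_column(features_path)
  barcodes <- read_id_column(barcodes_path)
  if (length(features) != nrow(sp))
    stop("features file has ", length(features), " entries but matrix has ",
         nrow(sp), " rows", call. = FALSE)
  if (length(barcodes) != ncol(sp))
    stop("barcodes file has ", length(barcodes), " entries but matrix has ",
         ncol(sp), " columns", call. = FALSE)
  expr_matrix(as.matrix(sp), features, barcodes, kind = "counts")
}

# first field of each line, so 10x-style multi-column features.tsv also works
read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

fmt_num <- function(x) {
  # full-precision serialization: integers as integers, doubles round-trip safe
  ifelse(is.finite(x) & x == round(x) & abs(x) < 2^53,
         sprintf("%.0f", x), sprintf("%.17g", x))
}

#' Write a count or normalized matrix to disk
#'
#' The inverse of [read_counts()]: values are serialized at full precision so
#' that a write/read round trip is the numeric identity for both formats.
#'
#' @param matrix An `expr_matrix`.
#' @param path Output path.
#' @param format `"delimited"` or `"mtx_triplet"`.
#' @param delim Optional delimiter override (delimited format).
#' @param features_path,barcodes_path Companion output paths for
#'   `mtx_triplet`; default to `<path>.features.tsv` / `<path>.barcodes.tsv`.
#' @return The path, invisibly.
#' @export
write_counts <- function(matrix, path, format = c("delimited", "mtx_triplet"),
                         delim = NULL, features_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  if (format == "delimited") {
    writeLines(serialize_matrix_delim(matrix, infer_delim(path, delim)), path)
  } else {
    features_path <- features_path %||% paste0(path, ".features.tsv")
    barcodes_path <- barcodes_path %||% paste0(path, ".barcodes.tsv")
    v <- unclass(matrix)
    idx <- which(v != 0, arr.ind = TRUE)
    hdr <- c("%%MatrixMarket matrix coordinate real general",
             paste(nrow(v), ncol(v), nrow(idx)))
    entries <- if (nrow(idx)) {
      paste(idx[, 1], idx[, 2], fmt_num(v[idx]))
    } else character(0)
    writeLines(c(hdr, entries), path)
    writeLines(feature_ids(matrix), features_path)
    writeLines(sample_ids(matrix), barcodes_path)
  }
  invisible(path)
}

serialize_matrix_delim <- function(matrix, delim = "\t") {
  header <- paste(c("feature_id", sample_ids(matrix)), collapse = delim)
  if (!nrow(matrix)) return(header)
  v <- unclass(matrix)
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(feature_ids(matrix)[i], fmt_num(v[i, ])), collapse = delim)
  }, character(1))
  c(header, rows)
}

parse_matrix_delim <- function(lines, kind = "counts", delim = "\t") {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  m <- read_counts_delimited(tmp, delim)
  expr_matrix(unclass(m), feature_ids(m), sample_ids(m), kind = kind)
}

#' Read a sample design table
#'
#' @param path CSV file with a header; a `sample` column and a `condition`
#'   column are required, `batch` and any further columns are kept as-is.
#' @return A tibble keyed by `sample`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_design(df)
}

#' Validate a data frame as a design table
#'
#' @param df Data frame with `sample` and `condition` columns.
#' @return A tibble with unique samples.
#' @export
as_design <- function(df) {
  if (!"sample" %in% names(df))
    stop("design table must have a 'sample' column", call. = FALSE)
  if (!"condition" %in% names(df))
    stop("design table must have a 'condition' column", call. = FALSE)
  df$sample <- as.character(df$sample)
  dup <- df$sample[duplicated(df$sample)]
  if (length(dup))
    stop("duplicate sample ID in design: '", dup[[1]], "'", call. = FALSE)
  tibble::as_tibble(df)
}

#' Bind a design table to a matrix
#'
#' Checks that every matrix sample appears exactly once in the design and
#' returns the design rows in matrix sample order.
#'
#' @param matrix An `expr_matrix`.
#' @param design A design tibble from [read_design()] / [as_design()].
#' @return The design tibble reordered to match `sample_ids(matrix)`.
#' @export
bind_design <- function(matrix, design) {
  design <- as_design(design)
  missing <- setdiff(sample_ids(matrix), design$sample)
  if (length(missing))
    stop("sample '", missing[[1]], "' is in the matrix but not in the design",
         call. = FALSE)
  design[match(sample_ids(matrix), design$sample), , drop = FALSE]
}

#' Merge two expression matrices
#'
#' `axis = "samples"` binds columns (both matrices must cover the same
#' feature set; the feature order of `a` is kept); `axis = "features"` binds
#' rows over an identical sample set. Overlapping IDs on the merge axis are
#' an error; nothing is silently renamed.
#'
#' @param a,b Count `expr_matrix` objects.
#' @param axis `"samples"` or `"features"`.
#' @return The merged `expr_matrix`.
#' @export
merge_matrices <- function(a, b, axis = c("samples", "features")) {
  axis <- match.arg(axis)
  if (matrix_kind(a) != "counts" || matrix_kind(b) != "counts")
    stop("merge_matrices requires kind = counts on both inputs", call. = FALSE)
  if (axis == "samples") {
    diff <- c(setdiff(feature_ids(a), feature_ids(b)),
              setdiff(feature_ids(b), feature_ids(a)))
    if (length(diff))
      stop("feature sets differ: '", diff[[1]], "' is not shared", call. = FALSE)
    overlap <- intersect(sample_ids(a), sample_ids(b))
    if (length(overlap))
      stop("overlapping sample ID: '", overlap[[1]], "'", call. = FALSE)
    b_al <- unclass(b)[feature_ids(a), , drop = FALSE]
    expr_matrix(cbind(unclass(a), b_al), feature_ids(a),
                c(sample_ids(a), sample_ids(b)), kind = "counts")
  } else {
    diff <- c(setdiff(sample_ids(a), sample_ids(b)),
              setdiff(sample_ids(b), sample_ids(a)))
    if (length(diff))
      stop("sample sets differ: '", diff[[1]], "' is not shared", call. = FALSE)
    overlap <- intersect(feature_ids(a), feature_ids(b))
    if (length(overlap))
      stop("overlapping feature ID: '", overlap[[1]], "'", call. = FALSE)
    b_al <- unclass(b)[, sample_ids(a), drop = FALSE]
    expr_matrix(rbind(unclass(a), b_al),
                c(feature_ids(a), feature_ids(b)), sample_ids(a),
                kind = "counts")
  }
}

#' Partition features into spike-in controls and biological features
#'
#' Synthetic spike-in mixes (ERCC and similar) are identified by an ID
#' prefix. An empty spike set is valid.
#'
#' @param matrix An `expr_matrix`.
#' @param prefix Spike-in ID prefix (default `"ERCC-"`).
#' @return A list with `spike_feature_ids` and `biological_feature_ids`,
#'   disjoint sets whose union is all features.
#' @export
detect_spike_ins <- function(matrix, prefix = "ERCC-") {
  ids <- feature_ids(matrix)
  is_spike <- startsWith(ids, prefix)
  structure(list(spike_feature_ids = ids[is_spike],
                 biological_feature_ids = ids[!is_spike]),
            class = "spike_partition")
}

#' @export
print.spike_partition <- function(x, ...) {
  cat("<spike_partition> ", length(x$spike_feature_ids), " spike-in, ",
      length(x$biological_feature_ids), " biological features\n", sep = "")
  invisible(x)
}

#' Read gene lengths
#'
#' @param path Two-column TSV: feature ID, length in bases.
#' @return A named numeric vector of positive lengths.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("gene length file needs two columns", call. = FALSE)
  lens <- as.numeric(df[[2]])
  names(lens) <- as.character(df[[1]])
  check_gene_lengths(lens)
  lens
}

check_gene_lengths <- function(lengths) {
  if (anyNA(lengths) || any(lengths <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  check_unique_ids(names(lengths), "feature (length table)")
  invisible(lengths)
}

#' Read a plain-text gene list (one ID per line)
#'
#' @param path Text file.
#' @return Character vector of IDs.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  trimws(lines[nzchar(trimws(lines))])
}
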