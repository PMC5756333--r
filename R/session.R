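ARCHIVE_FORMAT_VERSION <- 1L

# canonical JSON shape for parameter records: live maps may hold atomic
# vectors where loaded maps hold lists; a JSON round trip makes both
# serialize identically
canonicalize_params <- function(p) {
  if (!length(p)) return(p)
  jsonlite::fromJSON(jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA,
                                      null = "null"),
                     simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

md5_string <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeChar(x, tmp, eos = NULL)
  unname(tools::md5sum(tmp))
}

serialize_table <- function(df) {
  df <- as.data.frame(df)
  types <- vapply(df, function(col) class(col)[[1]], character(1))
  cells <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  header <- paste(names(df), collapse = "\t")
  rows <- if (nrow(df)) {
    do.call(paste, c(cells, sep = "\t"))
  } else {
    character(0)
  }
  list(types = as.list(types), tsv = paste(c(header, rows), collapse = "\n"))
}

parse_table <- function(spec) {
  lines <- strsplit(spec$tsv, "\n", fixed = TRUE)[[1]]
  cols <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  types <- unlist(spec$types)
  body <- lines[-1]
  cells <- strsplit(body, "\t", fixed = TRUE)
  out <- lapply(seq_along(cols), function(j) {
    raw <- vapply(cells, `[[`, character(1), j)
    switch(types[[j]],
           numeric = as.numeric(raw),
           integer = as.integer(raw),
           logical = as.logical(raw),
           raw)
  })
  names(out) <- cols
  if (!length(body)) {
    out <- lapply(seq_along(cols), function(j)
      switch(types[[j]], numeric = numeric(0), integer = integer(0),
             logical = logical(0), character(0)))
    names(out) <- cols
  }
  tibble::as_tibble(out)
}

#' Save a session archive
#'
#' Serializes the whole data map — structure, operation records, recipes,
#' every node's matrix and every attached report — into a single JSON
#' document with embedded TSV payloads and per-payload md5 checksums. Given
#' identical inputs (and a frozen clock for the operation timestamps) the
#' byte layout is deterministic, so save/load/save round trips are
#' byte-identical.
#'
#' @param map A `data_map`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_state <- function(map, path) {
  node_manifest <- lapply(map$node_order, function(id) {
    node <- map$nodes[[id]]
    payload <- paste(serialize_matrix_delim(node$matrix), collapse = "\n")
    list(node_id = id, label = node$label, note = node$note,
         n_features = node$n_features, n_samples = node$n_samples,
         kind = matrix_kind(node$matrix),
         payload = payload, checksum = md5_string(payload),
         reports = lapply(node$reports, function(r) {
           list(recipe_id = r$recipe_id, produced_on = r$produced_on,
                failed = isTRUE(r$failed), body = r$body,
                tables = lapply(r$tables, serialize_table))
         }))
  })
  edge_manifest <- lapply(map$edges, function(e) {
    list(parent = e$parent, child = e$child,
         op = list(op_name = e$op$op_name,
                   params = canonicalize_params(e$op$params),
                   timestamp = e$op$timestamp))
  })
  ctx <- list()
  if (!is.null(map$context$design)) {
    ctx$design <- serialize_table(map$context$design)
  }
  if (!is.null(map$context$lengths)) {
    ctx$lengths <- serialize_table(
      tibble::tibble(feature_id = names(map$context$lengths),
                     length = unname(map$context$lengths)))
  }
  if (!is.null(map$context$network)) {
    net <- map$context$network
    ctx$network <- list(directed = net$directed,
                        tf_set = as.list(net$tf_set),
                        nodes = as.list(igraph::V(net$graph)$name),
                        edges = serialize_table(network_edges(net)))
  }
  manifest <- list(
    format_version = ARCHIVE_FORMAT_VERSION,
    root_id = map$root_id,
    active_id = map$active_id,
    counter = map$counter,
    recipes = lapply(map$recipes, function(r) {
      list(recipe_id = r$recipe_id, analysis_name = r$analysis_name,
           params = canonicalize_params(r$params))
    }),
    nodes = node_manifest,
    edges = edge_manifest,
    context = ctx)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeChar(paste0(as.character(json), "\n"), path, eos = NULL)
  invisible(path)
}

#' Load a session archive
#'
#' Reconstructs the data map saved by [save_state()], verifying the format
#' version and every payload checksum, and re-checks the map invariants.
#'
#' @param path Archive path.
#' @return A `data_map` with the saved active node restored.
#' @export
load_state <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  manifest <- jsonlite::fromJSON(readChar(path, file.size(path)),
                                 simplifyVector = FALSE)
  ver <- manifest$format_version
  if (is.null(ver) || ver > ARCHIVE_FORMAT_VERSION)
    stop("unsupported archive format version: ", ver %||% "none", call. = FALSE)
  map <- new.env(parent = emptyenv())
  class(map) <- "data_map"
  map$clock <- iso_now
  map$counter <- as.integer(manifest$counter)
  map$root_id <- manifest$root_id
  map$active_id <- manifest$active_id
  map$recipes <- lapply(manifest$recipes, function(r) {
    list(recipe_id = r$recipe_id, analysis_name = r$analysis_name,
         params = r$params)
  })
  map$nodes <- list()
  map$node_order <- character(0)
  for (nm in manifest$nodes) {
    if (is.null(nm$payload))
      stop("archive is missing the matrix payload for node '", nm$node_id,
           "'", call. = FALSE)
    if (!identical(md5_string(nm$payload), nm$checksum))
      stop("checksum mismatch for node '", nm$node_id, "'", call. = FALSE)
    m <- parse_matrix_delim(strsplit(nm$payload, "\n", fixed = TRUE)[[1]],
                            kind = nm$kind)
    node <- make_node(nm$node_id, nm$label, m)
    node$note <- nm$note %||% ""
    if (node$n_features != nm$n_features || node$n_samples != nm$n_samples)
      stop("dimension record does not match payload for node '", nm$node_id,
           "'", call. = FALSE)
    node$reports <- lapply(nm$reports, function(r) {
      rep <- new_report(r$recipe_id, r$produced_on, r$body,
                        lapply(r$tables, parse_table))
      rep$failed <- isTRUE(r$failed)
      rep
    })
    map$nodes[[nm$node_id]] <- node
    map$node_order <- c(map$node_order, nm$node_id)
  }
  map$edges <- lapply(manifest$edges, function(e) {
    list(parent = e$parent, child = e$child,
         op = operation(e$op$op_name, e$op$params, e$op$timestamp))
  })
  map$context <- list(design = NULL, network = NULL, lengths = NULL)
  ctx <- manifest$context
  if (!is.null(ctx$design)) map$context$design <- as_design(parse_table(ctx$design))
  if (!is.null(ctx$lengths)) {
    lt <- parse_table(ctx$lengths)
    map$context$lengths <- stats::setNames(lt$length, lt$feature_id)
  }
  if (!is.null(ctx$network)) {
    edges <- parse_table(ctx$network$edges)
    g <- igraph::graph_from_data_frame(
      as.data.frame(edges), directed = isTRUE(ctx$network$directed),
      vertices = data.frame(name = unlist(ctx$network$nodes)))
    map$context$network <- structure(
      list(graph = g, directed = isTRUE(ctx$network$directed),
           tf_set = sort(unlist(ctx$network$tf_set))),
      class = "regulatory_network")
  }
  validate_map(map)
  map
}

validate_map <- function(map) {
  if (!map$root_id %in% names(map$nodes))
    stop("root node missing from archive", call. = FALSE)
  if (!map$active_id %in% names(map$nodes))
    stop("active node missing from archive", call. = FALSE)
  if (!is_acyclic(map)) stop("derivation graph is cyclic", call. = FALSE)
  for (id in names(map$nodes)) {
    node <- map$nodes[[id]]
    if (node$n_features != nrow(node$matrix) ||
        node$n_samples != ncol(node$matrix))
      stop("node '", id, "' dimension mismatch", call. = FALSE)
    if (id != map$root_id && !length(parents_of(map, id)))
      stop("non-root node '", id, "' has no parent", call. = FALSE)
    if (id == map$root_id && length(parents_of(map, id)))
      stop("root node has a parent", call. = FALSE)
  }
  invisible(map)
}

#' Assemble a node's reports into one markdown document
#'
#' Concatenates the node's attached reports, each prefixed by its recipe
#' name and full parameter record, preceded by the node's lineage path from
#' the root.
#'
#' @param map A `data_map`.
#' @param node_id Node ID.
#' @return A single markdown string.
#' @export
assemble_report <- function(map, node_id) {
  check_node(map, node_id)
  node <- map$nodes[[node_id]]
  path <- lineage_path(map, node_id)
  path_lines <- vapply(path, function(id) {
    n <- map$nodes[[id]]
    in_edges <- Filter(function(e) e$child == id, map$edges)
    op_txt <- if (length(in_edges)) {
      op <- in_edges[[1]]$op
      paste0(" <- ", op$op_name, " ",
             as.character(jsonlite::toJSON(op$params, auto_unbox = TRUE,
                                           digits = NA)))
    } else " (root)"
    paste0("- ", n$label, " [", id, "] (", n$n_features, " x ", n$n_samples,
           ")", op_txt)
  }, character(1))
  recipe_name <- function(rid) {
    for (r in map$recipes) if (identical(r$recipe_id, rid)) return(r$analysis_name)
    "standalone"
  }
  sections <- vapply(node$reports, function(r) {
    paste(c(paste0("# Report: ", recipe_name(r$recipe_id),
                   " (", r$recipe_id %||% "standalone", ")"),
            "", r$body), collapse = "\n")
  }, character(1))
  note <- if (nzchar(node$note)) c("", paste0("Note: ", node$note)) else character(0)
  paste(c(paste0("# Node ", node$label, " (", node_id, ")"),
          note, "", "## Lineage", "", path_lines, "", sections),
        collapse = "\n")
}

lineage_path <- function(map, node_id) {
  path <- node_id
  cur <- node_id
  while (cur != map$root_id) {
    cur <- parents_of(map, cur)[[1]]
    path <- c(cur, path)
  }
  path
}
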