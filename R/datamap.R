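#' Operation record
#'
#' Every edge of the data map carries one of these: the operation name, its
#' parameters (serializable scalars and lists, sufficient to recompute the
#' child from the parent), and a timestamp.
#'
#' @param op_name Non-empty operation name.
#' @param params Named list of serializable parameters.
#' @param timestamp ISO-8601 string; if `NULL` it is filled in from the
#'   map's clock when the operation is recorded.
#' @return An `operation_record`.
#' @export
operation <- function(op_name, params = list(), timestamp = NULL) {
  if (!nzchar(op_name)) stop("op_name must be non-empty", call. = FALSE)
  structure(list(op_name = op_name, params = params, timestamp = timestamp),
            class = "operation_record")
}

new_report <- function(recipe_id, produced_on, body, tables = list()) {
  structure(list(recipe_id = recipe_id, produced_on = produced_on,
                 body = body, tables = tables),
            class = "cf_report")
}

#' @export
print.cf_report <- function(x, ...) {
  cat(x$body, "\n")
  invisible(x)
}

iso_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Create a data map
#'
#' The data map records the provenance of every derived dataset in a
#' session: nodes are datasets, edges carry the operations that derived
#' them. One node is "active"; registered analysis recipes are re-run
#' against the active node whenever it changes, and their reports are
#' attached to that node. The object is environment-backed: operations
#' mutate it in place and return the values documented on each operation.
#'
#' @param root_matrix The original `expr_matrix`.
#' @param label Label for the root node.
#' @param clock Zero-argument function returning an ISO-8601 timestamp
#'   string; inject a constant for deterministic archives.
#' @return A `data_map`.
#' @export
create_map <- function(root_matrix, label = "root", clock = iso_now) {
  map <- new.env(parent = emptyenv())
  map$nodes <- list()
  map$node_order <- character(0)
  map$edges <- list()
  map$recipes <- list()
  map$counter <- 0L
  map$clock <- clock
  map$context <- list(design = NULL, network = NULL, lengths = NULL)
  class(map) <- "data_map"
  id <- next_node_id(map)
  map$nodes[[id]] <- make_node(id, label, root_matrix)
  map$node_order <- id
  map$root_id <- id
  map$active_id <- id
  map
}

next_node_id <- function(map) {
  id <- paste0("n", map$counter)
  map$counter <- map$counter + 1L
  id
}

make_node <- function(id, label, matrix) {
  if (!nzchar(label)) stop("node label must be non-empty", call. = FALSE)
  list(node_id = id, label = label, note = "", matrix = matrix,
       n_features = nrow(matrix), n_samples = ncol(matrix),
       reports = list())
}

check_node <- function(map, node_id) {
  if (!node_id %in% names(map$nodes))
    stop("unknown node: '", node_id, "'", call. = FALSE)
  invisible(node_id)
}

#' Attach session context used by analysis recipes
#'
#' @param map A `data_map`.
#' @param design Optional design tibble.
#' @param network Optional `regulatory_network`.
#' @param lengths Optional named gene-length vector.
#' @return The map, invisibly.
#' @export
set_context <- function(map, design = NULL, network = NULL, lengths = NULL) {
  if (!is.null(design)) map$context$design <- as_design(design)
  if (!is.null(network)) map$context$network <- network
  if (!is.null(lengths)) map$context$lengths <- lengths
  invisible(map)
}

#' @export
print.data_map <- function(x, ...) {
  cat("<data_map> ", length(x$nodes), " node(s), ", length(x$edges),
      " edge(s), ", length(x$recipes), " recipe(s); active = ", x$active_id,
      "\n", sep = "")
  print(lineage_table(x))
  invisible(x)
}

#' Derive a new dataset node
#'
#' Adds `result` as a child of `parent_id` with an edge carrying the
#' operation record. The active node is unchanged.
#'
#' @param map A `data_map`.
#' @param parent_id Existing node ID.
#' @param op An [operation()] record.
#' @param result The derived `expr_matrix`.
#' @param label Node label.
#' @return The new node's ID.
#' @export
derive <- function(map, parent_id, op, result, label) {
  check_node(map, parent_id)
  add_child(map, list(parent_id), op, result, label)
}

#' Derive a node from several parents (merge)
#'
#' @param map A `data_map`.
#' @param parent_ids At least two distinct existing node IDs.
#' @param op An [operation()] record shared by all incoming edges.
#' @param result The merged `expr_matrix`.
#' @param label Node label.
#' @return The new node's ID.
#' @export
derive_merge <- function(map, parent_ids, op, result, label) {
  if (anyDuplicated(parent_ids))
    stop("duplicate parent IDs", call. = FALSE)
  if (length(parent_ids) < 2)
    stop("derive_merge needs at least 2 parents", call. = FALSE)
  for (p in parent_ids) check_node(map, p)
  add_child(map, as.list(parent_ids), op, result, label)
}

add_child <- function(map, parent_ids, op, result, label) {
  if (is.null(op$timestamp)) op$timestamp <- map$clock()
  id <- next_node_id(map)
  map$nodes[[id]] <- make_node(id, label, result)
  map$node_order <- c(map$node_order, id)
  for (p in parent_ids) {
    map$edges[[length(map$edges) + 1L]] <- list(parent = p, child = id, op = op)
  }
  stopifnot(is_acyclic(map))
  id
}

map_igraph <- function(map) {
  el <- if (length(map$edges)) {
    do.call(rbind, lapply(map$edges, function(e) c(e$parent, e$child)))
  } else {
    matrix(character(0), ncol = 2)
  }
  igraph::graph_from_data_frame(
    as.data.frame(el, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = names(map$nodes), stringsAsFactors = FALSE))
}

is_acyclic <- function(map) {
  !length(map$edges) || igraph::is_dag(map_igraph(map))
}

parents_of <- function(map, node_id) {
  unique(vapply(Filter(function(e) e$child == node_id, map$edges),
                `[[`, character(1), "parent"))
}

children_of <- function(map, node_id) {
  unique(vapply(Filter(function(e) e$parent == node_id, map$edges),
                `[[`, character(1), "child"))
}

#' Rename a node
#'
#' @param map A `data_map`.
#' @param node_id Node to rename.
#' @param label New non-empty label.
#' @return The map, invisibly.
#' @export
rename_node <- function(map, node_id, label) {
  check_node(map, node_id)
  if (!nzchar(label)) stop("node label must be non-empty", call. = FALSE)
  map$nodes[[node_id]]$label <- label
  invisible(map)
}

#' Attach a free-text note to a node
#'
#' @param map A `data_map`.
#' @param node_id Node to annotate.
#' @param note Note text.
#' @return The map, invisibly.
#' @export
annotate_node <- function(map, node_id, note) {
  check_node(map, node_id)
  map$nodes[[node_id]]$note <- note
  invisible(map)
}

#' Delete a node and all its descendants
#'
#' Children are defined only relative to their parent data, so deletion
#' cascades to the descendant closure. If the active node is removed, the
#' root becomes active. The root itself cannot be deleted.
#'
#' @param map A `data_map`.
#' @param node_id Node to delete.
#' @return Character vector of removed node IDs.
#' @export
delete_node <- function(map, node_id) {
  check_node(map, node_id)
  if (node_id == map$root_id) stop("cannot delete the root node", call. = FALSE)
  # breadth-first descendant closure on the edge list
  closure <- character(0)
  queue <- node_id
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur %in% closure) next
    closure <- c(closure, cur)
    queue <- c(queue, children_of(map, cur))
  }
  map$nodes[closure] <- NULL
  map$node_order <- setdiff(map$node_order, closure)
  map$edges <- Filter(function(e) !(e$parent %in% closure || e$child %in% closure),
                      map$edges)
  if (map$active_id %in% closure) map$active_id <- map$root_id
  stopifnot(is_acyclic(map))
  closure
}

#' Lineage table
#'
#' One row per node in topological order: identity, parents, the deriving
#' operation and its parameters (JSON-serialized), dimensions and timestamp.
#'
#' @param map A `data_map`.
#' @return A tibble.
#' @export
lineage_table <- function(map) {
  topo <- topo_order(map)
  rows <- lapply(topo, function(id) {
    node <- map$nodes[[id]]
    in_edges <- Filter(function(e) e$child == id, map$edges)
    op <- if (length(in_edges)) in_edges[[1]]$op else NULL
    tibble::tibble(
      node_id = id,
      label = node$label,
      parent_ids = paste(parents_of(map, id), collapse = ","),
      op_name = if (is.null(op)) "" else op$op_name,
      params = if (is.null(op)) "" else
        as.character(jsonlite::toJSON(op$params, auto_unbox = TRUE, digits = NA)),
      n_features = node$n_features,
      n_samples = node$n_samples,
      timestamp = if (is.null(op)) "" else op$timestamp)
  })
  dplyr::bind_rows(rows)
}

topo_order <- function(map) {
  if (!length(map$edges)) return(map$node_order)
  g <- map_igraph(map)
  ord <- igraph::topo_sort(g, mode = "out")
  names(ord)
}

#' @exportS3Method generics::tidy
tidy.data_map <- function(x, ...) lineage_table(x)

#' Export the lineage table as TSV
#'
#' @param map A `data_map`.
#' @param path Output path.
#' @export
write_lineage <- function(map, path) {
  utils::write.table(as.data.frame(lineage_table(map)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Get a node's matrix
#'
#' @param map A `data_map`.
#' @param node_id Node ID (default: active node).
#' @return The node's `expr_matrix`.
#' @export
node_matrix <- function(map, node_id = map$active_id) {
  check_node(map, node_id)
  map$nodes[[node_id]]$matrix
}

#' Get a node's attached reports
#'
#' @param map A `data_map`.
#' @param node_id Node ID (default: active node).
#' @return List of `cf_report` objects.
#' @export
node_reports <- function(map, node_id = map$active_id) {
  check_node(map, node_id)
  map$nodes[[node_id]]$reports
}

#' Register an analysis recipe
#'
#' Recipes are global to the map: every registered recipe is re-run against
#' the active matrix whenever the active node changes.
#'
#' @param map A `data_map`.
#' @param analysis_name One of `"sample_qc_stats"`, `"rank_frequency"`,
#'   `"mean_variability"`, `"mwu_de"`, `"tf_influence"`, `"feature_query"`.
#' @param params Named list of analysis parameters.
#' @return The recipe ID.
#' @export
add_recipe <- function(map, analysis_name, params = list()) {
  registered <- c("sample_qc_stats", "rank_frequency", "mean_variability",
                  "mwu_de", "tf_influence", "feature_query")
  if (!analysis_name %in% registered)
    stop("unknown analysis: '", analysis_name, "'", call. = FALSE)
  recipe_id <- paste0("r", length(map$recipes))
  map$recipes[[length(map$recipes) + 1L]] <-
    list(recipe_id = recipe_id, analysis_name = analysis_name, params = params)
  recipe_id
}

#' Switch the active node and re-run all recipes
#'
#' Sets the active node and eagerly re-executes every registered recipe
#' against its matrix. Fresh reports replace any previous report from the
#' same recipe on that node and are returned in recipe order. A recipe whose
#' preconditions fail on the new node (for example, a DE recipe after sample
#' filtering left a single condition) produces a failure report rather than
#' an error.
#'
#' @param map A `data_map`.
#' @param node_id Node to activate.
#' @return List of `cf_report` objects in recipe order.
#' @export
set_active <- function(map, node_id) {
  check_node(map, node_id)
  map$active_id <- node_id
  reports <- lapply(map$recipes, function(recipe) run_recipe(map, recipe, node_id))
  keep_ids <- setdiff(
    vapply(map$nodes[[node_id]]$reports, `[[`, character(1), "recipe_id"),
    vapply(map$recipes, `[[`, character(1), "recipe_id"))
  old <- Filter(function(r) r$recipe_id %in% keep_ids,
                map$nodes[[node_id]]$reports)
  map$nodes[[node_id]]$reports <- c(old, reports)
  reports
}

run_recipe <- function(map, recipe, node_id) {
  m <- map$nodes[[node_id]]$matrix
  params <- recipe$params
  result <- tryCatch(
    switch(recipe$analysis_name,
      sample_qc_stats = {
        tab <- sample_qc_stats(m)
        list(body = c("QC statistics per sample:", "", md_table(tab)),
             tables = list(qc = tab))
      },
      rank_frequency = {
        sid <- params$sample_id %||% sample_ids(m)[[1]]
        tab <- rank_frequency(m, sid)
        list(body = c(paste0("Rank-frequency table for sample ", sid, ":"),
                      "", md_table(utils::head(tab, 20))),
             tables = list(rank_frequency = tab))
      },
      mean_variability = {
        tab <- mean_variability(m)
        list(body = c("Per-feature mean/sd/cv:", "",
                      md_table(utils::head(tab, 20))),
             tables = list(mean_variability = tab))
      },
      mwu_de = {
        groups <- recipe_groups(map, m, params)
        de <- mwu_de(m, groups, pseudocount = params$pseudocount %||% 1)
        rep <- de_report(de, alpha = params$alpha %||% 0.05,
                         top_n = params$top_n %||% 100)
        list(body = rep$body, tables = c(rep$tables, list(de_table = tidy(de))))
      },
      tf_influence = {
        net <- map$context$network
        if (is.null(net)) stop("no network attached to the map", call. = FALSE)
        groups <- recipe_groups(map, m, params)
        de <- mwu_de(m, groups, pseudocount = params$pseudocount %||% 1)
        gs <- gene_scores(de, option = params$score_option %||% "lfc_times_logp")
        inf <- influence_scores(net, gs,
                                option = params$influence_option %||% "degree_normalized",
                                tau = params$tau %||% 1)
        list(body = c("TF influence ranking:", "",
                      md_table(utils::head(inf, 20))),
             tables = list(influence = tibble::as_tibble(inf)))
      },
      feature_query = {
        tab <- feature_query(m, params$target,
                             method = params$method %||% "pearson",
                             top_n = params$top_n %||% 20)
        list(body = c(paste0("Features correlated with ", params$target, ":"),
                      "", md_table(tab)),
             tables = list(query = tab))
      }),
    error = function(e) {
      list(body = paste0("Analysis '", recipe$analysis_name,
                         "' failed: ", conditionMessage(e)),
           tables = list(), failed = TRUE)
    })
  rep <- new_report(recipe$recipe_id, node_id,
                    paste(c(paste0("## ", recipe$analysis_name),
                            "",
                            paste0("Parameters: ",
                                   jsonlite::toJSON(params, auto_unbox = TRUE)),
                            "", result$body), collapse = "\n"),
                    result$tables)
  rep$failed <- isTRUE(result$failed)
  rep
}

recipe_groups <- function(map, m, params) {
  if (!is.null(params$groups)) return(params$groups)
  design <- map$context$design
  if (is.null(design)) stop("no design attached to the map", call. = FALSE)
  design <- design[design$sample %in% sample_ids(m), ]
  col <- params$group_by %||% "condition"
  labels <- design[[col]]
  if (length(unique(labels)) < 2) stop("fewer than two groups", call. = FALSE)
  stats::setNames(as.character(labels), design$sample)
}

# ---- replayable operations -------------------------------------------------

# Applies an operation record to its parent matrices; the single code path
# used both by the dm_* wrappers when the node is first derived and by
# replay_node(), so replay reproduces stored matrices exactly.
apply_operation <- function(op, inputs, context = list()) {
  p <- op$params
  m <- inputs[[1]]
  switch(op$op_name,
    normalize = {
      res <- normalize_counts(m, method = p$method,
                              min_detect_frac = p$min_detect_frac %||% 1,
                              trim_m = p$trim_m %||% 0.30,
                              trim_a = p$trim_a %||% 0.05,
                              spike_prefix = p$spike_prefix %||% "ERCC-",
                              lengths = context$lengths,
                              log = isTRUE(p$log),
                              pseudocount = p$pseudocount %||% 1)
      res$matrix
    },
    filter_features = {
      crit <- feature_criteria(min_mean_expr = p$min_mean_expr,
                               min_count = p$min_count,
                               min_samples = p$min_samples %||% 1,
                               keep_list = unlist(p$keep_list),
                               drop_list = unlist(p$drop_list))
      filter_features(m, crit)$matrix
    },
    filter_samples = {
      crit <- sample_criteria(total_range = unlist(p$total_range),
                              detected_range = unlist(p$detected_range),
                              max_dropout = p$max_dropout,
                              size_factor_range = unlist(p$size_factor_range),
                              keep_list = unlist(p$keep_list),
                              drop_list = unlist(p$drop_list))
      qc <- sample_qc_stats(m, sf = if (!is.null(p$sf_method))
        normalize_counts(m, method = p$sf_method)$size_factors else NULL)
      filter_samples(m, crit, qc)$matrix
    },
    subset = subset_matrix(m, features = unlist(p$feature_ids),
                           samples = unlist(p$sample_ids)),
    merge = Reduce(function(a, b) merge_matrices(a, b, axis = p$axis), inputs),
    stop("operation '", op$op_name, "' is not replayable", call. = FALSE))
}

#' Recompute a node's matrix by replaying its ancestry
#'
#' Re-applies every operation record on the path(s) from the root matrix to
#' the node. For any map built through the `dm_*` wrappers this reproduces
#' the stored matrix exactly.
#'
#' @param map A `data_map`.
#' @param node_id Node to replay.
#' @return The recomputed `expr_matrix`.
#' @export
replay_node <- function(map, node_id) {
  check_node(map, node_id)
  if (node_id == map$root_id) return(map$nodes[[map$root_id]]$matrix)
  in_edges <- Filter(function(e) e$child == node_id, map$edges)
  op <- in_edges[[1]]$op
  inputs <- lapply(in_edges, function(e) replay_node(map, e$parent))
  apply_operation(op, inputs, context = map$context)
}

# ---- compute-and-record wrappers -------------------------------------------

#' Derive a normalized child node
#'
#' Computes the normalization and records it on the map in one step, so the
#' operation record is guaranteed to replay to the stored matrix.
#'
#' @param map A `data_map`.
#' @param parent_id Parent node.
#' @param method Normalization method (see [normalize_counts()]).
#' @param label Node label (defaults to the method name).
#' @param ... Passed to [normalize_counts()].
#' @return The new node ID.
#' @export
dm_normalize <- function(map, parent_id, method, label = method, ...) {
  res <- normalize_counts(node_matrix(map, parent_id), method = method,
                          lengths = map$context$lengths, ...)
  derive(map, parent_id, res$op, res$matrix, label)
}

#' Derive a feature-filtered child node
#'
#' @param map A `data_map`.
#' @param parent_id Parent node.
#' @param criteria A [feature_criteria()] object.
#' @param label Node label.
#' @return The new node ID.
#' @export
dm_filter_features <- function(map, parent_id, criteria,
                               label = "feature filter") {
  res <- filter_features(node_matrix(map, parent_id), criteria)
  op <- operation("filter_features", Filter(Negate(is.null), unclass(criteria)))
  derive(map, parent_id, op, res$matrix, label)
}

#' Derive a sample-filtered child node
#'
#' @param map A `data_map`.
#' @param parent_id Parent node.
#' @param criteria A [sample_criteria()] object.
#' @param sf_method Optional size-factor method used for the QC statistics
#'   (needed when `size_factor_range` is active).
#' @param label Node label.
#' @return The new node ID.
#' @export
dm_filter_samples <- function(map, parent_id, criteria, sf_method = NULL,
                              label = "sample filter") {
  m <- node_matrix(map, parent_id)
  sf <- if (!is.null(sf_method)) normalize_counts(m, method = sf_method)$size_factors
  res <- filter_samples(m, criteria, sample_qc_stats(m, sf))
  params <- Filter(Negate(is.null), unclass(criteria))
  params$sf_method <- sf_method
  op <- operation("filter_samples", params)
  derive(map, parent_id, op, res$matrix, label)
}

#' Derive a subset child node
#'
#' @param map A `data_map`.
#' @param parent_id Parent node.
#' @param feature_ids,sample_ids Optional ID vectors to keep (NULL = all).
#' @param label Node label.
#' @return The new node ID.
#' @export
dm_subset <- function(map, parent_id, feature_ids = NULL, sample_ids = NULL,
                      label = "subset") {
  m <- subset_matrix(node_matrix(map, parent_id), feature_ids, sample_ids)
  op <- operation("subset", Filter(Negate(is.null),
                                   list(feature_ids = feature_ids,
                                        sample_ids = sample_ids)))
  derive(map, parent_id, op, m, label)
}

#' Derive a merge node from several parents
#'
#' @param map A `data_map`.
#' @param parent_ids At least two node IDs.
#' @param axis `"samples"` or `"features"`.
#' @param label Node label.
#' @return The new node ID.
#' @export
dm_merge <- function(map, parent_ids, axis = "samples", label = "merge") {
  mats <- lapply(parent_ids, function(p) node_matrix(map, p))
  m <- Reduce(function(a, b) merge_matrices(a, b, axis = axis), mats)
  derive_merge(map, parent_ids, operation("merge", list(axis = axis)), m, label)
}
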