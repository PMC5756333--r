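#' Construct a regulatory network
#'
#' Wraps an igraph graph with the set of nodes treated as transcription
#' factors. Directed graphs model regulator-to-target relationships
#' (RegNetwork-style); undirected graphs model protein-association networks
#' (STRING-style). Self-loops are dropped with a warning and duplicate edges
#' are collapsed.
#'
#' @param edges Data frame with columns `source`, `target` and optionally
#'   `weight`.
#' @param directed Logical.
#' @param tf_set Optional character vector of TF node names; defaults to all
#'   nodes with out-degree > 0 (directed) or all nodes (undirected).
#' @return A `regulatory_network`.
#' @export
regulatory_network <- function(edges, directed, tf_set = NULL) {
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop(s)", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  key <- if (directed) {
    paste(edges$source, edges$target)
  } else {
    paste(pmin(edges$source, edges$target), pmax(edges$source, edges$target))
  }
  edges <- edges[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = directed)
  if (is.null(tf_set)) {
    tf_set <- if (directed) {
      names(which(igraph::degree(g, mode = "out") > 0))
    } else {
      igraph::V(g)$name
    }
  } else {
    unknown <- setdiff(tf_set, igraph::V(g)$name)
    if (length(unknown)) {
      warning(length(unknown), " TF(s) absent from the network ignored: '",
              unknown[[1]], "'", if (length(unknown) > 1) ", ..." else "",
              call. = FALSE)
      tf_set <- intersect(tf_set, igraph::V(g)$name)
    }
  }
  structure(list(graph = g, directed = directed, tf_set = sort(tf_set)),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges, ",
      if (x$directed) "directed" else "undirected", ", ",
      length(x$tf_set), " TFs\n", sep = "")
  invisible(x)
}

#' Edge list of a network as a tibble
#'
#' @param net A `regulatory_network`.
#' @return Tibble with `source`, `target` (and `weight` if present).
#' @export
network_edges <- function(net) {
  df <- igraph::as_data_frame(net$graph, what = "edges")
  names(df)[1:2] <- c("source", "target")
  tibble::as_tibble(df)
}

#' Read a network from a TSV edge list
#'
#' @param path TSV with at least two columns (source, target, optional
#'   numeric weight). Lines with fewer than two fields raise an error with
#'   the line number.
#' @param directed Logical.
#' @param tf_list Optional path to a plain-text TF list (one gene per line).
#' @return A `regulatory_network`.
#' @export
read_network <- function(path, directed, tf_list = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad))
    stop("malformed network line ", bad[[1]], ": fewer than 2 fields",
         call. = FALSE)
  edges <- data.frame(
    source = vapply(fields, `[[`, character(1), 1L),
    target = vapply(fields, `[[`, character(1), 2L),
    stringsAsFactors = FALSE)
  if (all(lengths(fields) >= 3)) {
    w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    if (!anyNA(w)) edges$weight <- w
  }
  tfs <- if (!is.null(tf_list)) read_gene_list(tf_list) else NULL
  regulatory_network(edges, directed = directed, tf_set = tfs)
}

#' Gene scores from a differential-expression result
#'
#' Converts the per-feature DE statistics into the non-negative gene scores
#' used for network influence ranking. `lfc_times_logp` (the default) scores
#' a gene by `|log2 FC| * -log10(adjusted p)`, combining effect size and
#' significance; `abs_lfc` and `neglogp` use each term alone. Adjusted
#' p-values are floored at `p_floor` so the score stays finite.
#'
#' @param de A `de_result`.
#' @param option `"lfc_times_logp"`, `"abs_lfc"` or `"neglogp"`.
#' @param p_floor Lower bound for adjusted p (default 1e-300).
#' @return A `gene_score_table`: tibble `(gene, score)` with the scoring
#'   parameters attached. Genes not listed score 0 downstream.
#' @export
gene_scores <- function(de, option = c("lfc_times_logp", "abs_lfc", "neglogp"),
                        p_floor = 1e-300) {
  option <- match.arg(option)
  tab <- tidy(de)
  p <- pmax(tab$p_adjusted, p_floor)
  score <- switch(option,
    lfc_times_logp = abs(tab$log2_fc) * (-log10(p)),
    abs_lfc = abs(tab$log2_fc),
    neglogp = -log10(p))
  out <- tibble::tibble(gene = tab$feature_id, score = score)
  structure(out, score_option = option, p_floor = p_floor,
            class = c("gene_score_table", class(out)))
}

#' Build a gene score table from explicit scores
#'
#' @param scores Named numeric vector (names = genes) of non-negative scores.
#' @param option Label recorded as the scoring option.
#' @return A `gene_score_table`.
#' @export
as_gene_scores <- function(scores, option = "manual") {
  if (any(!is.finite(scores)) || any(scores < 0))
    stop("gene scores must be finite and non-negative", call. = FALSE)
  out <- tibble::tibble(gene = names(scores), score = unname(scores))
  structure(out, score_option = option, p_floor = NA_real_,
            class = c("gene_score_table", class(out)))
}

score_lookup <- function(scores) {
  function(genes) {
    s <- scores$score[match(genes, scores$gene)]
    s[is.na(s)] <- 0
    s
  }
}

#' Induced subgraph of top-ranked genes
#'
#' Zooms the network to the regulatory "hot spot": the subgraph induced by
#' genes passing both an absolute fold-change and an adjusted-p threshold.
#'
#' @param net A `regulatory_network`.
#' @param de A `de_result`.
#' @param min_abs_lfc Minimum `|log2 FC|`.
#' @param max_p Maximum adjusted p.
#' @return A `regulatory_network` on the passing genes (possibly empty, with
#'   a warning).
#' @export
top_subgraph <- function(net, de, min_abs_lfc = 1, max_p = 0.05) {
  tab <- tidy(de)
  pass <- tab$feature_id[abs(tab$log2_fc) >= min_abs_lfc &
                           tab$p_adjusted <= max_p]
  keep <- intersect(pass, igraph::V(net$graph)$name)
  if (!length(keep)) {
    warning("no gene passes the thresholds; returning an empty network",
            call. = FALSE)
  }
  sub <- igraph::induced_subgraph(net$graph, keep)
  structure(list(graph = sub, directed = net$directed,
                 tf_set = intersect(net$tf_set, keep)),
            class = "regulatory_network")
}

tf_neighbors <- function(net, tf) {
  mode <- if (net$directed) "out" else "all"
  setdiff(names(igraph::neighbors(net$graph, tf, mode = mode)), tf)
}

#' Network influence scores for transcription factors
#'
#' Ranks TFs as candidate trans-differentiation factors by aggregating the
#' gene scores of each TF and its direct neighborhood (out-neighbors in a
#' directed network, all neighbors in an undirected one). Three aggregation
#' options: `sum` adds the center and all neighbor scores;
#' `degree_normalized` (default) divides each neighbor's score by that
#' neighbor's in-degree (degree if undirected), so a target regulated by many
#' TFs shares its credit; `activated_count` counts neighbors whose score
#' reaches `tau`. The activated-neighbor count is reported for every option.
#'
#' @param net A `regulatory_network` with a non-empty TF set.
#' @param scores A `gene_score_table`.
#' @param option `"sum"`, `"degree_normalized"` or `"activated_count"`.
#' @param tau Activation threshold on the gene score (default 1).
#' @return A `tf_influence_table`: tibble with `tf`, `center_score`,
#'   `neighborhood_size`, `activated_neighbors`, `influence_score`, `rank`
#'   (descending score; ties broken by center score then gene name).
#' @export
influence_scores <- function(net, scores,
                             option = c("degree_normalized", "sum",
                                        "activated_count"),
                             tau = 1) {
  option <- match.arg(option)
  if (!length(net$tf_set)) stop("the network has no TFs", call. = FALSE)
  lookup <- score_lookup(scores)
  deg_mode <- if (net$directed) "in" else "all"
  rows <- lapply(net$tf_set, function(tf) {
    nb <- tf_neighbors(net, tf)
    g_center <- lookup(tf)
    g_nb <- lookup(nb)
    activated <- sum(g_nb >= tau)
    s <- switch(option,
      sum = g_center + sum(g_nb),
      degree_normalized = {
        d <- if (length(nb)) igraph::degree(net$graph, nb, mode = deg_mode) else numeric(0)
        g_center + sum(g_nb / d)
      },
      activated_count = activated)
    tibble::tibble(tf = tf, center_score = g_center,
                   neighborhood_size = length(nb),
                   activated_neighbors = activated,
                   influence_score = s)
  })
  out <- dplyr::bind_rows(rows)
  ord <- order(-out$influence_score, -out$center_score, out$tf)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out <- dplyr::arrange(out, .data$rank)
  structure(out, option = option, tau = tau,
            class = c("tf_influence_table", class(out)))
}

#' @exportS3Method generics::glance
glance.tf_influence_table <- function(x, ...) {
  tibble::tibble(option = attr(x, "option"), tau = attr(x, "tau"),
                 n_tf = nrow(x), top_tf = x$tf[x$rank == 1])
}

#' Local neighborhood of a TF with scores attached
#'
#' The subgraph induced by a TF and its direct neighbors, exportable for
#' plotting: a node table carrying each gene's score and the induced edge
#' list.
#'
#' @param net A `regulatory_network`.
#' @param scores A `gene_score_table`.
#' @param tf A TF in the network's TF set.
#' @return A list with `nodes` (tibble `gene`, `score`, `is_center`) and
#'   `edges` (tibble `source`, `target`).
#' @export
tf_neighborhood <- function(net, scores, tf) {
  if (!tf %in% net$tf_set) stop("unknown TF: '", tf, "'", call. = FALSE)
  nb <- tf_neighbors(net, tf)
  nodes <- c(tf, nb)
  sub <- igraph::induced_subgraph(net$graph, nodes)
  lookup <- score_lookup(scores)
  edges <- igraph::as_data_frame(sub, what = "edges")
  list(nodes = tibble::tibble(gene = nodes, score = lookup(nodes),
                              is_center = nodes == tf),
       edges = tibble::tibble(source = as.character(edges$from),
                              target = as.character(edges$to)))
}

#' Export a TF neighborhood as an edge-list + node-score TSV pair
#'
#' @param nbhd Result of [tf_neighborhood()].
#' @param edges_path,nodes_path Output paths.
#' @export
write_tf_neighborhood <- function(nbhd, edges_path, nodes_path) {
  utils::write.table(as.data.frame(nbhd$edges), edges_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(nbhd$nodes), nodes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(edges_path)
}

#' Export a TF influence table as TSV
#'
#' @param x A `tf_influence_table`.
#' @param path Output path.
#' @export
write_influence_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
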