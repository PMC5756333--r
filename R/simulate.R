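#' Simulation specification for synthetic count matrices
#'
#' Defines a zero-inflated negative-binomial count generator with the
#' statistical structure the toolkit assumes: per-gene log-normal baseline
#' means, per-sample log-normal size factors, two balanced conditions, a
#' fraction of genes carrying planted log2 fold changes, an optional
#' logistic-in-log-mean dropout model emulating single-cell zero inflation,
#' and spike-in rows at fixed known concentrations that scale only with the
#' size factor (no differential expression, no dropout).
#'
#' @param n_features,n_samples Matrix dimensions (biological features;
#'   spike-ins are added on top).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters for gene
#'   baseline means (natural-log scale).
#' @param sf_sdlog Log-normal sigma for the true size factors
#'   (`meanlog = 0`).
#' @param dispersion Negative-binomial dispersion phi (`var = m + phi m^2`);
#'   0 gives Poisson counts.
#' @param de_fraction Fraction pi of genes with a planted effect.
#' @param effect_mean,effect_sd Planted |log2 FC| ~ Normal(effect_mean,
#'   effect_sd), sign random.
#' @param dropout Enable the zero-inflation model.
#' @param dropout_a,dropout_b Dropout probability = `plogis(a - b * log(mean))`.
#' @param n_spikes Number of spike-in rows (IDs `ERCC-0001`, ...).
#' @param spike_concentrations Mean counts of the spike rows at size factor
#'   1; defaults to a 2-fold ladder starting at 4.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_features = 2000, n_samples = 20,
                            baseline_meanlog = 1.5, baseline_sdlog = 1,
                            sf_sdlog = 0.3, dispersion = 0.1,
                            de_fraction = 0.1, effect_mean = 2,
                            effect_sd = 0.5,
                            dropout = FALSE, dropout_a = 1.5, dropout_b = 1,
                            n_spikes = 0,
                            spike_concentrations = 4 * 2^(seq_len(n_spikes) - 1)) {
  stopifnot(n_features >= 1, n_samples >= 2,
            baseline_sdlog > 0, sf_sdlog >= 0, dispersion >= 0,
            de_fraction >= 0, de_fraction <= 1, n_spikes >= 0)
  structure(list(n_features = n_features, n_samples = n_samples,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 sf_sdlog = sf_sdlog, dispersion = dispersion,
                 de_fraction = de_fraction, effect_mean = effect_mean,
                 effect_sd = effect_sd, dropout = dropout,
                 dropout_a = dropout_a, dropout_b = dropout_b,
                 n_spikes = n_spikes,
                 spike_concentrations = spike_concentrations),
            class = "simulation_spec")
}

rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a count matrix with known truth
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed; the output is fully deterministic given the
#'   seed.
#' @return A list with `matrix` (an `expr_matrix`, spike rows last),
#'   `design` (tibble: sample, condition) and `truth` (list: `size_factors`
#'   named vector, `de_genes` tibble of feature_id and true log2_fc,
#'   `spike_ids`).
#' @export
simulate_counts <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  nf <- spec$n_features; ns <- spec$n_samples
  gene_ids <- sprintf("gene%05d", seq_len(nf))
  samples <- sprintf("S%03d", seq_len(ns))
  cond <- rep(c(0L, 1L), length.out = ns)
  s <- stats::rlnorm(ns, 0, spec$sf_sdlog)
  s <- s / exp(mean(log(s)))
  mu0 <- stats::rlnorm(nf, spec$baseline_meanlog, spec$baseline_sdlog)
  n_de <- round(spec$de_fraction * nf)
  de_idx <- if (n_de) sample.int(nf, n_de) else integer(0)
  beta <- numeric(nf)
  if (n_de) {
    beta[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::rnorm(n_de, spec$effect_mean, spec$effect_sd)
  }
  mu <- outer(mu0, s) * 2^(outer(beta, cond))
  counts <- base::matrix(rnb(length(mu), as.vector(mu), spec$dispersion),
                         nrow = nf)
  if (spec$dropout) {
    p_zero <- stats::plogis(spec$dropout_a - spec$dropout_b * log(as.vector(mu)))
    counts[stats::runif(length(counts)) < p_zero] <- 0
  }
  spike_ids <- character(0)
  if (spec$n_spikes > 0) {
    spike_ids <- sprintf("ERCC-%04d", seq_len(spec$n_spikes))
    spike_mu <- outer(spec$spike_concentrations, s)
    spikes <- base::matrix(stats::rpois(length(spike_mu), as.vector(spike_mu)),
                           nrow = spec$n_spikes)
    counts <- rbind(counts, spikes)
  }
  m <- expr_matrix(counts, c(gene_ids, spike_ids), samples, kind = "counts")
  design <- tibble::tibble(sample = samples,
                           condition = ifelse(cond == 0, "A", "B"))
  truth <- list(size_factors = stats::setNames(s, samples),
                de_genes = tibble::tibble(feature_id = gene_ids[de_idx],
                                          log2_fc = beta[de_idx]),
                spike_ids = spike_ids)
  list(matrix = m, design = design, truth = truth)
}

#' Simulate a directed TF-to-target regulatory network
#'
#' Builds a random bipartite-leaning directed graph (each TF regulates a
#' Poisson-sized random subset of targets) together with a companion truth
#' gene-score table. With `planted_tf = TRUE` the first TF's targets receive
#' the top scores, so that TF should rank first under every influence
#' option.
#'
#' @param n_tf Number of transcription factors.
#' @param n_targets Number of target genes.
#' @param planted_tf Plant a top-scoring hub (default FALSE).
#' @param seed Integer seed.
#' @param mean_out_degree Mean number of targets per TF (default 5).
#' @return A list with `network` (a `regulatory_network`) and `scores` (a
#'   `gene_score_table`).
#' @export
simulate_network <- function(n_tf, n_targets, planted_tf = FALSE, seed = 1,
                             mean_out_degree = 5) {
  stopifnot(n_tf >= 1, n_targets >= 0)
  set.seed(seed)
  tfs <- sprintf("TF%03d", seq_len(n_tf))
  targets <- if (n_targets) sprintf("G%04d", seq_len(n_targets)) else character(0)
  edges <- NULL
  if (n_targets) {
    edges <- dplyr::bind_rows(lapply(tfs, function(tf) {
      k <- min(n_targets, stats::rpois(1, mean_out_degree) + 1L)
      tibble::tibble(source = tf, target = sample(targets, k))
    }))
  }
  score <- stats::setNames(stats::runif(n_targets, 0, 5), targets)
  tf_score <- stats::setNames(stats::runif(n_tf, 0, 1), tfs)
  if (planted_tf && !is.null(edges)) {
    # the planted hub must dominate every option: give it the largest
    # out-neighborhood and scores that outweigh full-credit unplanted ones
    # even after in-degree sharing
    other_deg <- if (n_tf > 1) {
      max(vapply(tfs[-1], function(tf) sum(edges$source == tf), integer(1)))
    } else 0L
    k1 <- min(n_targets, other_deg + 2L)
    edges <- edges[edges$source != tfs[[1]], , drop = FALSE]
    planted_targets <- sample(targets, k1)
    edges <- dplyr::bind_rows(
      tibble::tibble(source = tfs[[1]], target = planted_targets), edges)
    base_top <- (max(score[setdiff(targets, planted_targets)], 0) + 1) *
      n_tf * 2
    score[planted_targets] <- base_top + seq_along(planted_targets)
    tf_score[tfs[[1]]] <- max(tf_score) + 1
  }
  g <- if (is.null(edges)) {
    igraph::make_empty_graph(directed = TRUE) + igraph::vertices(tfs)
  } else {
    igraph::graph_from_data_frame(edges, directed = TRUE,
                                  vertices = data.frame(name = c(tfs, targets)))
  }
  net <- structure(list(graph = g, directed = TRUE, tf_set = tfs),
                   class = "regulatory_network")
  list(network = net, scores = as_gene_scores(c(tf_score, score), "simulated"))
}

#' Write a simulated dataset to disk
#'
#' Emits the counts (TSV or MTX triplet), the design CSV and the truth
#' tables (true size factors, true DE genes, spike IDs) so simulated data
#' can feed the command-line interface.
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @param format `"delimited"` or `"mtx_triplet"` for the counts.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, format = "delimited") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "delimited") {
    write_counts(sim$matrix, file.path(dir, "counts.tsv"), "delimited")
  } else {
    write_counts(sim$matrix, file.path(dir, "matrix.mtx"), "mtx_triplet",
                 features_path = file.path(dir, "features.tsv"),
                 barcodes_path = file.path(dir, "barcodes.tsv"))
  }
  utils::write.csv(as.data.frame(sim$design), file.path(dir, "design.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(c("sample\tfactor",
               paste(names(sim$truth$size_factors),
                     fmt_num(sim$truth$size_factors), sep = "\t")),
             file.path(dir, "true_size_factors.tsv"))
  utils::write.table(as.data.frame(sim$truth$de_genes),
                     file.path(dir, "true_de_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$spike_ids, file.path(dir, "spike_ids.txt"))
  invisible(dir)
}
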