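test_that("network reading drops self-loops, collapses duplicates, flags bad lines", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "C\tD"), path)
  net <- read_network(path, directed = TRUE)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_setequal(net$tf_set, c("A", "B", "C"))

  writeLines(c("A\tA", "A\tB"), path)
  expect_warning(net2 <- read_network(path, directed = TRUE), "self-loop")
  expect_equal(igraph::ecount(net2$graph), 1)

  writeLines(c("A\tB", "A\tB", "B\tA"), path)
  net3 <- read_network(path, directed = TRUE)
  expect_equal(igraph::ecount(net3$graph), 2)  # A->B deduplicated, B->A kept
  net3u <- read_network(path, directed = FALSE)
  expect_equal(igraph::ecount(net3u$graph), 1)  # undirected: all three collapse

  writeLines(c("A\tB", "loner"), path)
  expect_error(read_network(path, directed = TRUE), "line 2")

  tf_path <- withr::local_tempfile()
  writeLines(c("A", "ZZZ"), tf_path)
  writeLines(c("A\tB"), path)
  expect_warning(net4 <- read_network(path, directed = TRUE, tf_list = tf_path),
                 "absent")
  expect_identical(net4$tf_set, "A")
})

test_that("gene scores follow the three scoring options with a p floor", {
  de <- structure(list(table = tibble::tibble(
    feature_id = c("g1", "g2", "g3"),
    u_statistic = 0, p_value = c(0.01, 1, 0),
    p_adjusted = c(0.01, 1, 0),
    log2_fc = c(2, 3, 1), mean_a = 1, mean_b = 1, method = "exact"),
    group_a = "a", group_b = "b", n_a = 3, n_b = 3, pseudocount = 1),
    class = "de_result")
  gs <- gene_scores(de, "lfc_times_logp")
  expect_equal(gs$score[gs$gene == "g1"], 2 * 2)   # |lfc| * -log10(p)
  expect_equal(gs$score[gs$gene == "g2"], 0)       # p = 1
  expect_equal(gs$score[gs$gene == "g3"], 300)     # floored at 1e-300
  expect_equal(gene_scores(de, "abs_lfc")$score, c(2, 3, 1))
  expect_equal(gene_scores(de, "neglogp")$score, c(2, 0, 300))
  expect_true(all(is.finite(gs$score)))
})

test_that("influence scores reproduce the worked three-node example", {
  net <- worked_network()
  gs <- worked_scores()
  s_sum <- influence_scores(net, gs, "sum")
  expect_equal(s_sum$influence_score[s_sum$tf == "T"], 6)
  s_dn <- influence_scores(net, gs, "degree_normalized")
  expect_equal(s_dn$influence_score[s_dn$tf == "T"], 1 + 2 / 2 + 3 / 1)
  s_ac <- influence_scores(net, gs, "activated_count", tau = 2.5)
  expect_equal(s_ac$influence_score[s_ac$tf == "T"], 1)
  expect_equal(s_ac$activated_neighbors[s_ac$tf == "T"], 1)
  expect_equal(s_sum$neighborhood_size[s_sum$tf == "T"], 2)
})

test_that("an isolated TF scores only itself; zero scores rank by tie-break", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B"), directed = TRUE,
    vertices = data.frame(name = c("A", "B", "Z")))
  net <- structure(list(graph = g, directed = TRUE, tf_set = c("A", "Z")),
                   class = "regulatory_network")
  gs <- as_gene_scores(c(A = 0.5, B = 2, Z = 3))
  res <- influence_scores(net, gs, "sum")
  expect_equal(res$influence_score[res$tf == "Z"], 3)
  expect_equal(res$neighborhood_size[res$tf == "Z"], 0)

  zeros <- as_gene_scores(c(A = 0, B = 0, Z = 0))
  rz <- influence_scores(net, zeros, "sum")
  expect_equal(rz$influence_score, c(0, 0))
  expect_equal(rz$activated_neighbors, c(0, 0))
  expect_identical(rz$tf[rz$rank], c("A", "Z"))  # lexicographic tie-break
})

test_that("raising a neighbor's score never lowers sum or degree-normalized scores", {
  set.seed(17)
  for (i in 1:20) {
    sim <- simulate_network(n_tf = 5, n_targets = 15, seed = i)
    net <- sim$network; gs <- sim$scores
    base_sum <- influence_scores(net, gs, "sum")
    base_dn <- influence_scores(net, gs, "degree_normalized")
    bumped <- gs
    j <- sample(nrow(bumped), 1)
    bumped$score[j] <- bumped$score[j] + runif(1, 0.1, 5)
    up_sum <- influence_scores(net, bumped, "sum")
    up_dn <- influence_scores(net, bumped, "degree_normalized")
    expect_true(all(up_sum$influence_score[order(up_sum$tf)] >=
                      base_sum$influence_score[order(base_sum$tf)] - 1e-12))
    expect_true(all(up_dn$influence_score[order(up_dn$tf)] >=
                      base_dn$influence_score[order(base_dn$tf)] - 1e-12))
  }
})

test_that("degree-normalized credit is conserved across TFs", {
  # sum over TFs of (S_t - G_t) must equal the brute-force double loop
  for (seed in 1:5) {
    sim <- simulate_network(n_tf = 6, n_targets = 20, seed = seed)
    net <- sim$network; gs <- sim$scores
    res <- influence_scores(net, gs, "degree_normalized")
    lhs <- sum(res$influence_score - res$center_score)
    edges <- network_edges(net)
    lookup <- stats::setNames(gs$score, gs$gene)
    indeg <- table(edges$target)
    rhs <- 0
    for (k in seq_len(nrow(edges))) {
      j <- edges$target[k]
      rhs <- rhs + lookup[[j]] / as.numeric(indeg[[j]])
    }
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("a planted hub ranks first under all influence options", {
  for (seed in 1:3) {
    sim <- simulate_network(n_tf = 8, n_targets = 30, planted_tf = TRUE,
                            seed = seed)
    for (opt in c("sum", "degree_normalized", "activated_count")) {
      res <- influence_scores(sim$network, sim$scores, opt,
                              tau = stats::quantile(sim$scores$score, 0.8))
      expect_identical(res$tf[res$rank == 1], "TF001")
    }
  }
})

test_that("top_subgraph induces exactly the passing genes and their edges", {
  net <- regulatory_network(
    data.frame(source = c("A", "A", "B", "C"),
               target = c("B", "C", "D", "E")), directed = TRUE)
  de <- structure(list(table = tibble::tibble(
    feature_id = c("A", "B", "C", "D", "E"),
    u_statistic = 0, p_value = c(0.01, 0.01, 0.5, 0.9, 0.01),
    p_adjusted = c(0.01, 0.01, 0.5, 0.9, 0.01),
    log2_fc = c(3, 2, 0.1, 4, 2), mean_a = 1, mean_b = 1, method = "exact"),
    group_a = "a", group_b = "b", n_a = 3, n_b = 3, pseudocount = 1),
    class = "de_result")
  sub <- top_subgraph(net, de, min_abs_lfc = 1, max_p = 0.05)
  expect_setequal(igraph::V(sub$graph)$name, c("A", "B", "E"))
  el <- network_edges(sub)
  expect_equal(nrow(el), 1)  # only A->B survives induction
  expect_identical(c(el$source, el$target), c("A", "B"))

  all_in <- top_subgraph(net, de, min_abs_lfc = 0, max_p = 1)
  expect_equal(igraph::vcount(all_in$graph), 5)
  expect_warning(empty <- top_subgraph(net, de, min_abs_lfc = 100, max_p = 0),
                 "no gene passes")
  expect_equal(igraph::vcount(empty$graph), 0)
})

test_that("TF neighborhoods export the induced local subgraph with scores", {
  net <- worked_network()
  gs <- worked_scores()
  nb <- tf_neighborhood(net, gs, "T")
  expect_setequal(nb$nodes$gene, c("T", "a", "b"))
  expect_equal(nb$nodes$score[nb$nodes$gene == "b"], 3)
  expect_true(nb$nodes$is_center[nb$nodes$gene == "T"])
  expect_equal(nrow(nb$edges), 2)  # U->a is excluded (U outside neighborhood)
  expect_setequal(nb$edges$target, c("a", "b"))
  expect_error(tf_neighborhood(net, gs, "a"), "unknown TF")

  dir <- withr::local_tempdir()
  write_tf_neighborhood(nb, file.path(dir, "e.tsv"), file.path(dir, "n.tsv"))
  expect_equal(nrow(utils::read.delim(file.path(dir, "e.tsv"))), 2)
})
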