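test_that("graph construction applies the strict score threshold and keeps isolates", {
  e <- edge_list(c("A", "B", "C"), c("B", "C", "D"), c(0.15, 0.16, 0.9))
  g <- build_ppi_graph(e, c("A", "B", "C", "D", "E"), 0.15)
  expect_equal(igraph::vcount(g), 5L)                 # E isolated, A too
  expect_equal(igraph::ecount(g), 2L)                 # 0.15 excluded
  expect_equal(sum(igraph::degree(g) > 0), 3L)        # connectivity report
  expect_equal(unname(degree_centrality(g)["A"]), 0)
})

test_that("degree, betweenness and MNC match brute-force oracles", {
  # path A-B-C: B carries the single (A,C) shortest path
  p3 <- rand_graph(3, 0, 1)
  p3$adj[1, 2] <- p3$adj[2, 1] <- p3$adj[2, 3] <- p3$adj[3, 2] <- 1L
  g <- igraph::graph_from_adjacency_matrix(p3$adj, mode = "undirected")
  expect_equal(unname(betweenness_centrality(g)), c(0, 1, 0))
  # exhaustive: every labelled graph on 4 nodes
  combos <- expand.grid(rep(list(0:1), 6))
  for (r in seq_len(nrow(combos))) {
    adj <- matrix(0L, 4, 4)
    adj[upper.tri(adj)] <- as.integer(combos[r, ])
    adj <- adj + t(adj)
    dimnames(adj) <- list(paste0("n", 1:4), paste0("n", 1:4))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(degree_centrality(g)), rowSums(adj),
                 ignore_attr = TRUE)
    expect_equal(unname(betweenness_centrality(g)), bf_betweenness(adj),
                 tolerance = 1e-9)
    expect_equal(unname(mnc(g)),
                 vapply(1:4, function(v) as.integer(bf_mnc(adj, v)), 1L))
  }
  # random graphs on 5-7 nodes
  for (seed in 1:60) {
    n <- 5 + (seed %% 3)
    rg <- rand_graph(n, runif(1, 0.2, 0.8), seed)
    expect_equal(unname(degree_centrality(rg$g)), rowSums(rg$adj),
                 ignore_attr = TRUE)
    expect_equal(unname(betweenness_centrality(rg$g)),
                 bf_betweenness(rg$adj), tolerance = 1e-9)
    expect_equal(unname(mnc(rg$g)),
                 vapply(seq_len(n), function(v)
                   as.integer(bf_mnc(rg$adj, v)), 1L))
  }
})

test_that("MNC fixtures: triangle neighbourhood and star centre", {
  # v with 3 neighbours forming a triangle -> 3
  adj <- matrix(0L, 4, 4)
  adj[1, 2:4] <- adj[2:4, 1] <- 1L
  adj[2, 3] <- adj[3, 2] <- adj[3, 4] <- adj[4, 3] <- adj[2, 4] <- adj[4, 2] <- 1L
  dimnames(adj) <- list(paste0("n", 1:4), paste0("n", 1:4))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  expect_equal(unname(mnc(g))[1], 3L)
  # star centre with 5 leaves -> 1 (neighbours all isolated)
  star <- igraph::make_star(6, "undirected", center = 1)
  igraph::V(star)$name <- paste0("n", 1:6)
  expect_equal(unname(mnc(star))[1], 1L)
  expect_equal(unname(degree_centrality(star))[1], 5)
  # clique nodes have zero betweenness
  cl <- igraph::make_full_graph(5)
  igraph::V(cl)$name <- paste0("n", 1:5)
  expect_true(all(betweenness_centrality(cl) == 0))
})

test_that("EPC limiting cases are exact and the single-edge expectation holds", {
  rg <- rand_graph(8, 0.4, 3)
  comp <- igraph::components(rg$g)
  csize <- comp$csize[comp$membership]
  expect_equal(unname(epc(rg$g, replicates = 3, keep_prob = 1)),
               csize - 1, ignore_attr = TRUE)
  expect_equal(unname(epc(rg$g, replicates = 3, keep_prob = 0)),
               rep(0, 8))
  e <- edge_list("A", "B", 0.9)
  g2 <- build_ppi_graph(e, c("A", "B"))
  val <- epc(g2, replicates = 10000, keep_prob = 0.5, seed = 7)
  expect_lt(max(abs(val - 0.5)), 0.05)
  expect_error(epc(g2, keep_prob = 1.5), "keep_prob")
})

test_that("EPC is monotone non-decreasing in keep_prob", {
  rg <- rand_graph(9, 0.3, 12)
  probs <- c(0.25, 0.5, 0.75)
  vals <- sapply(probs, function(p)
    epc(rg$g, replicates = 10000, keep_prob = p, seed = 5))
  expect_true(all(vals[, 2] - vals[, 1] >= -0.02))
  expect_true(all(vals[, 3] - vals[, 2] >= -0.02))
})

test_that("EPC is deterministic given a seed", {
  rg <- rand_graph(10, 0.3, 4)
  expect_identical(epc(rg$g, 200, 0.5, seed = 42),
                   epc(rg$g, 200, 0.5, seed = 42))
})

test_that("MCODE resolves disjoint cliques and rejects sparse attachments", {
  # two disjoint 6-cliques: two complexes, each score 6, both reported
  adj <- matrix(0L, 12, 12)
  adj[1:6, 1:6] <- 1L; adj[7:12, 7:12] <- 1L; diag(adj) <- 0L
  dimnames(adj) <- list(sprintf("n%02d", 1:12), sprintf("n%02d", 1:12))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  res <- mcode(g)
  expect_equal(nrow(res$complexes), 2L)
  expect_equal(res$complexes$score, c(6, 6))
  expect_equal(res$complexes$n_nodes, c(6L, 6L))
  expect_true(all(res$complexes$score > 5))
  expect_equal(unname(res$node_score), rep(6, 12))
  # 6-clique with a pendant chain: the complex is the clique only
  adj2 <- matrix(0L, 9, 9)
  adj2[1:6, 1:6] <- 1L; diag(adj2) <- 0L
  adj2[6, 7] <- adj2[7, 6] <- adj2[7, 8] <- adj2[8, 7] <- 1L
  adj2[8, 9] <- adj2[9, 8] <- 1L
  dimnames(adj2) <- list(paste0("n", 1:9), paste0("n", 1:9))
  g2 <- igraph::graph_from_adjacency_matrix(adj2, mode = "undirected")
  res2 <- mcode(g2)
  expect_equal(nrow(res2$complexes), 1L)
  expect_identical(strsplit(res2$complexes$members, ";")[[1]],
                   paste0("n", 1:6))
  # max degree 1 -> no complex (degree cutoff 2)
  g3 <- igraph::graph_from_literal(a - b, c - d)
  expect_equal(nrow(mcode(g3)$complexes), 0L)
})

test_that("MCODE complexes are disjoint, dense and k-cored on random graphs", {
  for (seed in 1:10) {
    rg <- rand_graph(20, 0.35, 100 + seed)
    res <- mcode(rg$g, mcode_params(complex_score_min = 0.5))
    all_members <- unlist(res$membership)
    expect_equal(anyDuplicated(all_members), 0L)
    for (m in res$membership) {
      sub <- igraph::induced_subgraph(rg$g, m)
      dens <- 2 * igraph::ecount(sub) /
        (igraph::vcount(sub) * (igraph::vcount(sub) - 1))
      expect_gt(dens, 0)
      expect_lte(dens, 1)
      expect_gte(max(igraph::coreness(sub)), 2)
    }
  }
})

test_that("hub selection is the strict four-way top-n intersection", {
  set.seed(6)
  ct <- data.frame(protein = sprintf("p%02d", 1:15),
                   betweenness = runif(15), mnc = sample(1:10, 15, TRUE),
                   degree = sample(1:14, 15, TRUE), epc = runif(15) * 10,
                   mcode = 0)
  hs <- select_hubs(ct, top_n = 10)
  for (m in c("degree", "epc", "betweenness", "mnc"))
    expect_true(all(hs$hubs %in% hs$top[[m]]))
  expect_setequal(hs$hubs, Reduce(intersect, hs$top))
  # a node 11th on one metric is excluded even if 1st elsewhere
  ct2 <- data.frame(protein = sprintf("p%02d", 1:11),
                    betweenness = c(10:1, 11), mnc = 11:1,
                    degree = 11:1, epc = 11:1, mcode = 0)
  hs2 <- select_hubs(ct2, top_n = 10)
  expect_false("p11" %in% hs2$hubs)      # 1st on betweenness, 11th elsewhere
  expect_true("p01" %in% hs2$hubs)
  # fewer nodes than top_n: all nodes used
  hs3 <- select_hubs(ct2[1:4, ], top_n = 10)
  expect_setequal(hs3$hubs, ct2$protein[1:4])
})

test_that("ties in ranking break deterministically by node id", {
  ct <- data.frame(protein = c("b", "a", "c"),
                   betweenness = c(1, 1, 0), mnc = c(2, 2, 1),
                   degree = c(3, 3, 1), epc = c(4, 4, 1), mcode = 0)
  hs <- select_hubs(ct, top_n = 1)
  expect_identical(hs$hubs, "a")
})
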