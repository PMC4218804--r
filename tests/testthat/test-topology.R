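test_that("enzyme network construction follows the shared-metabolite rule", {
  lin <- make_toy_model("linear")$model
  g <- build_enzyme_network(lin)
  edges <- apply(igraph::as_edgelist(g), 1, function(e) paste(sort(e), collapse = "-"))
  expect_true("gA-gB" %in% edges)       # EX_A and R_AB share metabolite A
  expect_true("gB-gBIO" %in% edges)     # R_AB and BIO share metabolite B
  expect_false("gA-gBIO" %in% edges)    # no shared metabolite

  # excluding the shared metabolite removes the edge
  g2 <- build_enzyme_network(lin, excluded_metabolites = "A")
  edges2 <- apply(igraph::as_edgelist(g2), 1, function(e) paste(sort(e), collapse = "-"))
  expect_false("gA-gB" %in% edges2)

  # isozymes on one reaction are adjacent via the same-reaction rule,
  # even when every metabolite is excluded
  iso <- metabolic_model(
    "iso", data.frame(id = c("A", "B")),
    data.frame(id = c("EX", "R", "BIO"), lower_bound = 0, upper_bound = 10,
               gpr = c("", "g1 or g2", ""), objective_coefficient = c(0, 0, 1)),
    list(EX = c(A = 1), R = c(A = -1, B = 1), BIO = c(B = -1)))
  g3 <- build_enzyme_network(iso, excluded_metabolites = c("A", "B"))
  edges3 <- apply(igraph::as_edgelist(g3), 1, function(e) paste(sort(e), collapse = "-"))
  expect_equal(edges3, "g1-g2")

  # a model with no GPRs gives an empty graph and a warning
  bare <- metabolic_model(
    "bare", data.frame(id = "A"),
    data.frame(id = c("IN", "OUT"), lower_bound = 0, upper_bound = 10,
               objective_coefficient = c(0, 1)),
    list(IN = c(A = 1), OUT = c(A = -1)))
  expect_warning(g4 <- build_enzyme_network(bare), "empty")
  expect_equal(igraph::vcount(g4), 0)
})

test_that("closed-form centralities hold on K3 and P3", {
  k3 <- adjacency_to_igraph(matrix(1, 3, 3) - diag(3))
  t3 <- compute_centralities(k3)
  expect_equal(t3$Degree, rep(2, 3))
  expect_equal(t3$ClusteringCoefficient, rep(1, 3))
  expect_equal(t3$MCC, rep(2, 3))             # one maximal clique, (3-1)!
  expect_equal(t3$Betweenness, rep(0, 3))
  expect_equal(t3$Stress, rep(0, 3))
  expect_equal(t3$Eccentricity, rep(1, 3))
  expect_equal(t3$Closeness, rep(2, 3))

  p3 <- adjacency_to_igraph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  tp <- compute_centralities(p3)
  expect_equal(tp$Betweenness, c(0, 1, 0))
  expect_equal(tp$Stress, c(0, 1, 0))
  expect_equal(tp$Degree, c(1, 2, 1))
  expect_equal(tp$Eccentricity, c(2, 1, 2))
})

test_that("EPC at retention 1 equals the component size exactly", {
  adj <- random_adjacency(7, 0.3, seed = 5)
  g <- adjacency_to_igraph(adj)
  tab <- compute_centralities(
    g, centrality_config(epc_realizations = 10,
                         epc_retention_probability = 1, seed = 2))
  comp <- igraph::components(g)
  expect_equal(tab$EPC, unname(comp$csize[comp$membership]))
})

test_that("centrality scores are invariant under node relabeling", {
  adj <- random_adjacency(6, 0.5, seed = 9)
  g <- adjacency_to_igraph(adj)
  tab <- compute_centralities(g, centrality_config(epc_realizations = 4000,
                                                   seed = 4))
  set.seed(21)
  perm <- sample(6)
  adj2 <- adj[perm, perm]
  g2 <- adjacency_to_igraph(adj2, names = letters[1:6][perm])
  tab2 <- compute_centralities(g2, centrality_config(epc_realizations = 4000,
                                                     seed = 8))
  tab2 <- tab2[match(tab$node, tab2$node), ]
  for (idx in setdiff(names(tab), c("node", "EPC"))) {
    expect_equal(tab2[[idx]], tab[[idx]], tolerance = 1e-9,
                 label = paste("index", idx))
  }
  # EPC is Monte-Carlo: equal in expectation, compare within sampling error
  expect_equal(tab2$EPC, tab$EPC, tolerance = 0.2)
})

test_that("ranking is deterministic with id tie-breaks and k > n flags all", {
  tab <- compute_centralities(adjacency_to_igraph(matrix(1, 3, 3) - diag(3)))
  rf <- rank_and_flag(tab, c("a", "b", "c"), k = 5)
  for (idx in names(rf$top_k)) {
    expect_setequal(rf$top_k[[idx]], c("a", "b", "c"))
    expect_setequal(rf$ranks[[idx]], 1:3)
  }
  # all scores tie on K3, so ranks follow node ids
  expect_equal(rf$ranks$Degree[match(c("a", "b", "c"), rf$ranks$node)], 1:3)

  # k = 2 on tied scores keeps the lexicographically smaller ids
  rf2 <- rank_and_flag(tab, c("a", "b", "c"), k = 2)
  expect_setequal(rf2$top_k$Degree, c("a", "b"))

  expect_warning(rf3 <- rank_and_flag(tab, "zz", k = 2), "disjoint")
  expect_length(rf3$top_k$Degree, 0)
})

test_that("singletons get the documented degenerate scores", {
  g <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(g)$name <- c("a", "b")
  tab <- compute_centralities(g, centrality_config(epc_realizations = 5))
  indices <- c("MCC", "DMNC", "MNC", "Degree", "BottleNeck", "Eccentricity",
               "Closeness", "Radiality", "Betweenness", "Stress",
               "ClusteringCoefficient")
  for (idx in indices) {
    expect_equal(tab[[idx]], c(0, 0), label = idx)
  }
  expect_equal(tab$EPC, c(1, 1))  # a node always reaches itself
})
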