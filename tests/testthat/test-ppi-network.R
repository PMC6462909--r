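test_that("build_network restricts, simplifies and drops isolates", {
  empty <- build_network(data.frame(node_a = character(0), node_b = character(0)),
                         restrict_to = c("A", "B"))
  expect_equal(igraph::vcount(empty), 0)

  df <- data.frame(node_a = c("A", "B", "A"), node_b = c("B", "B", "B"))
  expect_message(net <- build_network(df, restrict_to = c("A", "B")), "self-loop")
  expect_equal(igraph::vcount(net), 2)
  expect_equal(igraph::ecount(net), 1)

  df2 <- data.frame(node_a = c("A", "B", "C"), node_b = c("B", "C", "D"))
  net2 <- build_network(df2, restrict_to = c("A", "B", "C"))
  expect_setequal(igraph::V(net2)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(net2), 2)

  # scored edges honor min_score
  df3 <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"), score = c(0.9, 0.1))
  net3 <- build_network(df3, restrict_to = c("A", "B", "C"), min_score = 0.5)
  expect_equal(igraph::ecount(net3), 1)
})

test_that("edge lists round-trip through TSV with line-number errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("node_a\tnode_b", "A\tB", "B\tC"), f)
  df <- read_edge_list(f)
  expect_equal(nrow(df), 2)
  writeLines(c("A\tB", "oops"), f)
  expect_error(read_edge_list(f), "line 2", class = "lncnet_parse_error")
})

test_that("degree_table orders by degree then identifier", {
  expect_equal(nrow(degree_table(igraph::make_empty_graph(0))), 0)
  clique <- build_network(clique_edges(paste0("n", 1:5)), restrict_to = paste0("n", 1:5))
  expect_true(all(degree_table(clique)$degree == 4))
  path <- build_network(path_edges(c("A", "B", "C")), restrict_to = c("A", "B", "C"))
  dt <- degree_table(path)
  expect_equal(dt$node, c("B", "A", "C"))
  expect_equal(dt$degree, c(2L, 1L, 1L))
})

test_that("mcode vertex weights match hand-derived values", {
  ids <- paste0("c", 1:5)
  g <- build_network(clique_edges(ids), restrict_to = ids)
  expect_equal(mcode_vertex_weight(g, "c1"), 4)

  # degree-1 node hanging off the clique: 2-node closed neighborhood, weight 1
  pend <- rbind(clique_edges(ids), data.frame(node_a = "c1", node_b = "x"))
  gp <- build_network(pend, restrict_to = c(ids, "x"))
  expect_equal(mcode_vertex_weight(gp, "x"), 1)

  # isolated node (self-loop only input survives as nothing; build separately)
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "solo"
  expect_equal(mcode_vertex_weight(iso, "solo"), 0)
  expect_error(mcode_vertex_weight(g, "nope"), class = "lncnet_lookup_error")
})

test_that("a single 6-clique yields one module of score 6", {
  ids <- paste0("k", 1:6)
  g <- build_network(clique_edges(ids), restrict_to = ids)
  mods <- mcode_find_modules(g)
  expect_equal(nrow(mods), 1)
  expect_setequal(mods$members[[1]], ids)
  expect_equal(mods$score, 6)
  expect_equal(nrow(mcode_find_modules(igraph::make_empty_graph(0, directed = FALSE))), 0)
})

test_that("every returned module contains a k-core (pruning oracle) and is deterministic", {
  set.seed(31)
  for (rep in 1:5) {
    sim <- generate_ppi(60, 0.08, list(c(7, 0.95)), seed = 100 + rep)
    net <- build_network(sim$edges, restrict_to = unique(unlist(sim$edges)))
    mods <- mcode_find_modules(net, k_core = 3)
    for (m in mods$members)
      expect_true(has_kcore_oracle(m, sim$edges, 3))
    # module disjointness
    expect_false(anyDuplicated(unlist(mods$members)) > 0)
    # determinism
    expect_identical(mods, mcode_find_modules(net, k_core = 3))
  }
})

test_that("two equal 5-cliques joined by a bridge merge into one 4-core module", {
  # Under the stated expansion rule every node of both cliques has weight 4,
  # so expansion crosses the bridge: the result is a single module that is its
  # own 4-core covering both cliques (see the design notes on this choice).
  a <- paste0("a", 1:5); b <- paste0("b", 1:5)
  edges <- rbind(clique_edges(a), clique_edges(b),
                 data.frame(node_a = "a1", node_b = "b1"))
  net <- build_network(edges, restrict_to = c(a, b))
  mods <- mcode_find_modules(net, k_core = 4)
  expect_equal(nrow(mods), 1)
  expect_setequal(mods$members[[1]], c(a, b))
  expect_true(has_kcore_oracle(mods$members[[1]], edges, 4))
})

test_that("planted blocks of unequal size are recovered separately", {
  sim <- generate_ppi(200, 0.02, list(c(8, 0.95), c(6, 0.95)), seed = 7)
  net <- build_network(sim$edges, restrict_to = unique(unlist(sim$edges)))
  mods <- mcode_find_modules(net)
  for (blk in sim$truth$planted_modules) {
    best <- max(vapply(mods$members, jaccard, numeric(1), b = blk))
    expect_gte(best, 0.8)
  }
})

test_that("haircut trims singly-connected members", {
  ids <- paste0("c", 1:5)
  edges <- rbind(clique_edges(ids), data.frame(node_a = "c1", node_b = "tail"))
  net <- build_network(edges, restrict_to = c(ids, "tail"))
  # with a permissive cutoff the tail joins the candidate; haircut removes it
  mods <- mcode_find_modules(net, node_score_cutoff = 1)
  expect_false("tail" %in% unlist(mods$members))
  no_cut <- mcode_find_modules(net, node_score_cutoff = 1, haircut = FALSE)
  expect_true("tail" %in% unlist(no_cut$members))
})

test_that("module tables round-trip and nodes are annotated in three classes", {
  ids <- paste0("k", 1:6)
  extra <- data.frame(node_a = "k1", node_b = "out")
  net <- build_network(rbind(clique_edges(ids), extra), restrict_to = c(ids, "out"))
  mods <- mcode_find_modules(net)
  f <- tempfile(fileext = ".tsv")
  write_modules(mods, f)
  back <- read_modules(f)
  expect_equal(back$members[[1]], mods$members[[1]])

  ann <- annotate_targeted_nodes(net, mods, targeted = c("k1", "out"))
  expect_equal(ann$class[ann$node == "k1"], "targeted-in-module")
  expect_equal(ann$class[ann$node == "out"], "targeted-not-in-module")
  expect_equal(ann$class[ann$node == "k2"], "not-targeted")
  ann0 <- annotate_targeted_nodes(net, mods, character(0))
  expect_true(all(ann0$class == "not-targeted"))
})
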