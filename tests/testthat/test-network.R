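star_net <- function() {
  typed_network(data.frame(from = "H", to = c("A", "B", "C")),
                c(H = "target", A = "target", B = "target", C = "target"))
}

path_net <- function() {
  typed_network(data.frame(from = c("a", "b"), to = c("b", "c")),
                c(a = "target", b = "target", c = "target"))
}

test_that("typed network validates structure", {
  expect_error(typed_network(data.frame(from = "a", to = "a"),
                             c(a = "target")), "self-loop")
  expect_error(typed_network(data.frame(from = "a", to = "b"),
                             c(a = "target")), "without a role")
  expect_error(typed_network(data.frame(from = "a", to = "b"),
                             c(a = "gene", b = "target")), "roles")
  # duplicate unordered pairs collapse
  net <- typed_network(data.frame(from = c("a", "b"), to = c("b", "a")),
                       c(a = "target", b = "target"))
  expect_identical(igraph::ecount(net$graph), 1)
})

test_that("degree matches direct incidence counts", {
  m <- node_metrics(star_net())
  expect_identical(m$degree[m$node_id == "H"], 3L)
  expect_true(all(m$degree[m$node_id != "H"] == 1L))
  # isolated node has degree 0
  net <- typed_network(data.frame(from = "a", to = "b"),
                       c(a = "target", b = "target", z = "target"))
  m <- node_metrics(net)
  expect_identical(m$degree[m$node_id == "z"], 0L)
  # random graph: agree with per-node edge-list scan
  net <- rand_graph(30, 0.2, seed = 5)
  m <- node_metrics(net)
  ora <- oracle_degree(net)
  expect_identical(stats::setNames(as.numeric(m$degree), m$node_id),
                   ora[m$node_id])
  # handshake lemma
  expect_identical(sum(m$degree), 2L * as.integer(igraph::ecount(net$graph)))
})

test_that("betweenness and closeness reproduce hand-checkable graphs", {
  m <- node_metrics(path_net())
  expect_equal(m$betweenness[m$node_id == "b"], 1.0)
  expect_equal(m$betweenness[m$node_id %in% c("a", "c")], c(0, 0))
  expect_equal(m$closeness[m$node_id == "b"], 1 / 2)
  expect_equal(m$closeness[m$node_id == "a"], 1 / 3)
  # complete graph: no transit, closeness 1/(n-1)
  k4 <- typed_network(as.data.frame(t(combn(c("a", "b", "c", "d"), 2))),
                      stats::setNames(rep("target", 4),
                                      c("a", "b", "c", "d")))
  m4 <- node_metrics(k4)
  expect_true(all(m4$betweenness == 0))
  expect_true(all(m4$closeness == 1 / 3))
})

test_that("metrics equal brute-force path-enumeration oracles", {
  for (seed in 1:12) {
    net <- rand_graph(sample(4:14, 1), runif(1, 0.15, 0.5), seed = seed)
    m <- node_metrics(net)
    got_b <- stats::setNames(m$betweenness, m$node_id)
    got_c <- stats::setNames(m$closeness, m$node_id)
    ora_b <- oracle_betweenness(net)
    ora_c <- oracle_closeness(net)
    expect_equal(got_b[names(ora_b)], ora_b, tolerance = 1e-10)
    expect_equal(got_c[names(ora_c)], ora_c, tolerance = 1e-10)
    # normalized closeness against the oracle too
    mn <- node_metrics(net, closeness_mode = "normalized")
    got_cn <- stats::setNames(mn$closeness, mn$node_id)
    expect_equal(got_cn[names(ora_c)],
                 oracle_closeness(net, normalized = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("raw-count betweenness counts paths without the sigma ratio", {
  # path a-b-c: one transit path through b
  m <- node_metrics(path_net(), betweenness_mode = "count")
  expect_equal(m$betweenness[m$node_id == "b"], 1)
  # square a-b-c-d-a: two shortest a..c paths, each interior node
  # carries one full path (fractional mode would give 1/2)
  sq <- typed_network(data.frame(from = c("a", "b", "c", "d"),
                                 to = c("b", "c", "d", "a")),
                      stats::setNames(rep("target", 4), letters[1:4]))
  mc <- node_metrics(sq, betweenness_mode = "count")
  mf <- node_metrics(sq)
  expect_equal(mc$betweenness, rep(1, 4))
  expect_equal(mf$betweenness, rep(0.5, 4))
})

test_that("normalized betweenness divides by the pair count", {
  net <- rand_graph(10, 0.3, seed = 3)
  m <- node_metrics(net)
  mn <- node_metrics(net, normalized = TRUE)
  expect_equal(mn$betweenness, m$betweenness / (9 * 8 / 2))
})

test_that("threshold selection uses strict comparisons and the
           even-population median convention", {
  v <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  expect_identical(select_nodes_above(v), c("d", "e"))
  # all equal: strict selection is empty
  expect_identical(select_nodes_above(c(a = 2, b = 2, c = 2)),
                   character(0))
  # even count: median is the mean of the two central values (2.5)
  expect_identical(select_nodes_above(c(w = 1, x = 2, y = 3, z = 4)),
                   c("y", "z"))
  # non-strict keeps ties
  expect_identical(
    select_nodes_above(c(a = 1, b = 3, c = 3), strict = FALSE),
    c("b", "c"))
  expect_identical(select_nodes_above(v, statistic = "mean"),
                   c("d", "e"))
  expect_error(select_nodes_above(numeric(0)), "empty")
})

test_that("bipartite construction deduplicates and assigns roles", {
  net <- build_bipartite(data.frame(c("c1", "c1"), c("t1", "t1")))
  expect_identical(igraph::vcount(net$graph), 2)
  expect_identical(igraph::ecount(net$graph), 1)
  net2 <- build_bipartite(data.frame(c("c1", "c2"), c("t1", "t1")))
  m <- node_metrics(net2)
  expect_identical(m$degree[m$node_id == "T1"], 2L)
  expect_identical(sort(unique(m$role)), c("compound", "target"))
  expect_error(build_bipartite(data.frame("X1", "x1")), "identical")
})

test_that("metrics are invariant to input order", {
  pairs <- gen_bipartite(10, 30, 5, seed = 2)$pairs
  net1 <- build_bipartite(pairs)
  net2 <- build_bipartite(pairs[rev(seq_len(nrow(pairs))), 2:1][, 2:1])
  m1 <- node_metrics(net1)
  m2 <- node_metrics(net2)
  expect_equal(m1, m2)
})

test_that("network summary reports counts and per-role mean degrees", {
  net <- build_bipartite(data.frame(
    compound = c("c1", "c1", "c1", "c2"),
    target = c("t1", "t2", "t3", "t1")))
  s <- network_summary(net)
  expect_identical(s$n_nodes, 5)
  expect_identical(s$n_edges, 4)
  expect_identical(s$nodes_per_role, c(compound = 2L, target = 3L))
  expect_equal(s$mean_degree_per_role, c(compound = 2.0, target = 1.3))
  # empty network
  s0 <- network_summary(typed_network(data.frame(from = character(0),
                                                 to = character(0)),
                                      character(0)))
  expect_identical(s0$n_nodes, 0)
  expect_identical(s0$n_edges, 0)
})

test_that("SIF round-trips a typed network with roles", {
  path <- withr::local_tempfile(fileext = ".sif")
  net <- build_bipartite(gen_bipartite(5, 12, 4, seed = 9)$pairs)
  write_sif(net, path)
  back <- read_sif(path)
  expect_identical(sort(node_ids(back)), sort(node_ids(net)))
  expect_identical(node_roles(back)[sort(node_ids(back))],
                   node_roles(net)[sort(node_ids(net))])
  expect_identical(igraph::ecount(back$graph), igraph::ecount(net$graph))
  # isolated nodes survive the round trip
  iso <- typed_network(data.frame(from = "a", to = "b"),
                       c(a = "target", b = "target", z = "target"))
  write_sif(iso, path)
  expect_identical(sort(node_ids(read_sif(path))), c("a", "b", "z"))
  # malformed line count reported
  writeLines(c("a\tcompound-target\tb", "x\ty"), path)
  expect_error(read_sif(path), "line 2")
})

test_that("GraphML export carries the role attribute", {
  path <- withr::local_tempfile(fileext = ".graphml")
  net <- build_bipartite(data.frame(c("c1", "c2"), c("t1", "t1")))
  write_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::vertex_attr(g, "role"), c("compound", "target"))
})
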