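test_that("edge density counts distinct connections against n^2 with loops", {
  g3 <- igraph::graph_from_literal(A -+ B, B -+ C, C -+ A, A -+ A,
                                   simplify = FALSE)
  expect_equal(edge_density_loops(g3), 4 / 9)
  full <- igraph::make_full_graph(3, directed = TRUE, loops = TRUE)
  igraph::V(full)$name <- c("A", "B", "C")
  expect_equal(edge_density_loops(full), 1)
  empty <- igraph::make_empty_graph(5)
  igraph::V(empty)$name <- LETTERS[1:5]
  expect_equal(edge_density_loops(empty), 0)
  # undirected convention: theoretical max n(n+1)/2
  u <- igraph::graph_from_literal(A - B, B - C)
  expect_equal(edge_density_loops(u, convention = "undirected"), 2 / 6)
  expect_error(edge_density_loops(g3, subset = character(0)),
               "empty", class = "axenet_validation_error")
  expect_error(edge_density_loops(g3, subset = c("A", "Z")),
               class = "axenet_validation_error")
})

test_that("density ignores weights and multiplicity, and is monotone in edges", {
  tab <- make_table(
    make_record("P1", "a", c("Fltr", "Wash")),
    make_record("P2", "b", c("Fltr", "Wash")),  # duplicate transition
    make_record("P3", "c", c("Wash", "Mkpk")))
  net <- build_axenisation_network(tab, "diatoms")
  # 3 method nodes; distinct method-method edges: Fltr>Wash, Wash>Mkpk
  expect_equal(edge_density_loops(net), 2 / 9)
  # subset density
  expect_equal(edge_density_loops(net, subset = c("Fltr", "Wash")), 1 / 4)
  # adding an edge (new record with a new transition) cannot lower density
  tab2 <- make_table(
    make_record("P1", "a", c("Fltr", "Wash")),
    make_record("P2", "b", c("Fltr", "Wash")),
    make_record("P3", "c", c("Wash", "Mkpk")),
    make_record("P4", "d", c("Mkpk", "Fltr")))
  net2 <- build_axenisation_network(tab2, "diatoms")
  expect_gte(edge_density_loops(net2), edge_density_loops(net))
})

test_that("degree is in+out over distinct connections with the stated loop rule", {
  star <- igraph::graph_from_literal(A -+ B, A -+ C, A -+ D)
  ds <- degree_stats(star)
  expect_equal(ds$degrees[["A"]], 3)
  expect_equal(ds$median, 1)
  two <- igraph::graph_from_literal(A -+ B, B -+ A)
  expect_equal(degree_stats(two)$median, 2)
  # a loop adds one incoming and one outgoing connection
  loopg <- igraph::graph_from_literal(A -+ A, A -+ B, simplify = FALSE)
  expect_equal(degree_stats(loopg)$degrees[["A"]], 3)
  # median over an even node count can be a half-integer
  ring4 <- igraph::graph_from_literal(A -+ B, B -+ C, C -+ A, C -+ D,
                                      D -+ A, simplify = FALSE)
  expect_equal(degree_stats(ring4)$median, 2.5)
})

test_that("workflow-network degree medians include the incubation hub by default", {
  tab <- make_table(
    make_record("P1", "a", c("Fltr", "Wash")),
    make_record("P2", "b", c("Mkpk")))
  net <- build_axenisation_network(tab, "diatoms")
  with_sink <- degree_stats(net)                      # Fltr 1, Wash 2, Mkpk 1, INCB 2
  without <- degree_stats(net, include_sink = FALSE)  # Fltr 1, Wash 1, Mkpk 0
  expect_equal(with_sink$median, 1.5)
  expect_equal(without$median, 1)
})

test_that("modularity matches hand-computed and igraph values", {
  # one community is exactly 0
  g <- random_test_graph(7, 0.5, seed = 2)
  memb1 <- setNames(rep(1, 7), igraph::V(g)$name)
  expect_equal(modularity_q(g, memb1), 0)
  # two disjoint triangles split by component: Q = 0.5
  tri2 <- igraph::graph_from_literal(A - B, B - C, C - A, D - E, E - F, F - D)
  memb2 <- setNames(c(1, 1, 1, 2, 2, 2), LETTERS[1:6])
  expect_equal(modularity_q(tri2, memb2, weighted = FALSE), 0.5)
  # singleton partition of a loop-free graph is negative
  membS <- setNames(1:6, LETTERS[1:6])
  expect_lt(modularity_q(tri2, membS, weighted = FALSE), 0)
  # agreement with the independent igraph implementation, weighted + random
  for (seed in 1:20) {
    gg <- random_test_graph(6, 0.6, seed = seed)
    if (igraph::ecount(gg) == 0) next
    set.seed(seed + 100)
    memb <- setNames(sample(1:3, 6, replace = TRUE), igraph::V(gg)$name)
    expect_equal(modularity_q(gg, memb),
                 igraph::modularity(gg, memb, weights = igraph::E(gg)$weight),
                 tolerance = 1e-12)
  }
  expect_error(modularity_q(tri2, setNames(1:5, LETTERS[1:5])),
               "missing", class = "axenet_validation_error")
})

test_that("metrics report assembles the division statistics", {
  tab <- generate_master_table(synthetic_config(seed = 9))$table
  net <- build_axenisation_network(tab, "green_algae")
  part <- optimal_partition(to_undirected(net))
  rep <- metrics_report(net, part)
  expect_equal(rep$n_nodes, length(method_nodes(net)))
  expect_equal(rep$modularity_Q, part$Q)
  expect_true(rep$density >= 0 && rep$density <= 1)
  expect_equal(rep$convention, "directed")
})
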