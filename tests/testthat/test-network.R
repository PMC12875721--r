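test_that("a single workflow yields its chain of transitions plus the sink edge", {
  tab <- make_table(make_record("P1", "s", c("Fltr", "Wash", "Mkpk")))
  net <- build_axenisation_network(tab, "diatoms")
  expect_setequal(method_nodes(net), c("Fltr", "Wash", "Mkpk"))
  el <- igraph::as_data_frame(net$graph)
  expect_equal(nrow(el), 3)
  got <- setNames(el$weight, paste(el$from, el$to, sep = ">"))
  expect_equal(got[c("Fltr>Wash", "Wash>Mkpk", "Mkpk>INCB")],
               c(`Fltr>Wash` = 1, `Wash>Mkpk` = 1, `Mkpk>INCB` = 1))
})

test_that("network invariants hold: sink inflow, total weight, order invariance", {
  out <- generate_master_table(synthetic_config(seed = 3))
  tab <- out$table
  for (dv in c("diatoms", "green_algae")) {
    sub <- filter_division(tab, dv)
    net <- build_axenisation_network(tab, dv)
    el <- igraph::as_data_frame(net$graph)
    # every workflow ends in incubation exactly once
    expect_equal(sum(el$weight[el$to == incubation_code()]), nrow(sub))
    # total directed weight = sum of workflow lengths (terminal edge incl.)
    expect_equal(sum(el$weight), sum(lengths(sub$methods)))
    expect_setequal(method_nodes(net), unique(unlist(sub$methods)))
  }
  # shuffling record order changes nothing
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  class(shuffled) <- class(tab)
  n1 <- build_axenisation_network(tab, "diatoms")
  n2 <- build_axenisation_network(shuffled, "diatoms")
  expect_true(igraph::identical_graphs(n1$graph, n2$graph) ||
                isTRUE(all.equal(
                  igraph::as_data_frame(n1$graph)[
                    order(igraph::as_data_frame(n1$graph)$from,
                          igraph::as_data_frame(n1$graph)$to), ],
                  igraph::as_data_frame(n2$graph)[
                    order(igraph::as_data_frame(n2$graph)$from,
                          igraph::as_data_frame(n2$graph)$to), ],
                  check.attributes = FALSE)))
  expect_error(build_axenisation_network(tab[0, ], "diatoms"),
               class = "axenet_validation_error")
})

test_that("consecutive repeats become self-loops; undirected projection sums weights", {
  tab <- make_table(
    make_record("P1", "a", c("Wash", "Wash", "Fltr")),
    make_record("P2", "b", c("Fltr", "Wash")))
  net <- build_axenisation_network(tab, "diatoms")
  el <- igraph::as_data_frame(net$graph)
  expect_equal(el$weight[el$from == "Wash" & el$to == "Wash"], 1)
  # A->B:1 and B->A:1 collapse to one undirected edge of weight 2
  und <- to_undirected(net)
  uel <- igraph::as_data_frame(und)
  expect_equal(nrow(uel), 1)
  expect_equal(uel$weight, 2)
  expect_false(incubation_code() %in% igraph::V(und)$name)
  # loop kept only on request
  und_l <- to_undirected(net, keep_loops = TRUE)
  expect_equal(igraph::ecount(und_l), 2)
  # undirected edge count never exceeds directed edge count
  expect_lte(igraph::ecount(und_l),
             igraph::ecount(axenet:::method_graph(net)))
})

test_that("verification co-usage counts publications, pairs and groups", {
  tab <- make_table(
    make_record("P1", "a", "Fltr", verification = c("Plate", "Seq16")),
    make_record("P1", "b", "Wash", verification = c("Plate", "Seq16")),
    make_record("P2", "c", "Fltr", verification = c("Plate", "Epifl",
                                                    "Seq16")),
    make_record("P3", "d", "Mkpk", verification = "Light"))
  vn <- build_verification_network(tab)
  # publication-level: P1's two species rows count once
  expect_equal(vn$usage$n_publications[vn$usage$code == "Plate"], 2L)
  el <- igraph::as_data_frame(vn$graph)
  w <- el$weight[(el$from == "Plate" & el$to == "Seq16") |
                   (el$from == "Seq16" & el$to == "Plate")]
  expect_equal(w, 2)
  # 3-method publication contributes choose(3,2) pairs
  expect_equal(sum(el$weight), 1 + 3)
  groups <- setNames(vn$group_totals$n_publications, vn$group_totals$group)
  expect_equal(groups[["microscopy"]], 2L)  # P2 (Epifl) + P3 (Light)
  expect_equal(groups[["counting"]], 2L)
  expect_equal(groups[["sequencing"]], 2L)
})

test_that("exports produce readable GraphML, DOT and edge-list files", {
  tab <- make_table(make_record("P1", "s", c("Fltr", "Wash")))
  net <- build_axenisation_network(tab, "diatoms")
  gml <- withr::local_tempfile(fileext = ".graphml")
  dot <- withr::local_tempfile(fileext = ".dot")
  csv <- withr::local_tempfile(fileext = ".csv")
  export_network(net, gml, "graphml",
                 node_attrs = tibble::tibble(code = c("Fltr", "Wash"),
                                             rate = c(0.8, 0.5)))
  export_network(net, dot, "dot")
  export_network(net, csv, "edgelist_csv")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, c("Fltr", "Wash", "INCB"))
  expect_equal(sort(igraph::V(back)$rate), c(0.5, 0.8))
  expect_true(any(grepl("->", readLines(dot))))
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 2)
})
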