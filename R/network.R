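# Workflow networks: ordered method lists become weighted directed graphs.
# Each species-level record with methods m1..mk contributes the transitions
# m1->m2, ..., m(k-1)->mk and a terminal edge mk->INCB into the incubation
# sink; edge weight is the number of such transitions across records.
# Consecutive repeats of a method yield self-loops. The INCB sink is carried
# in the graph but excluded from method-node counts and density.

#' Build the axenisation workflow network for a division
#'
#' @param table A `master_table`.
#' @param division A division label, or `NULL` to use all records (used for
#'   synthetic-recovery analyses).
#' @return A `workflow_network`: list with `division`, `graph` (directed
#'   weighted igraph including the `INCB` sink), `n_records` and
#'   `n_publications`.
#' @export
#' @examples
#' tab <- generate_master_table(synthetic_config(seed = 1))$table
#' net <- build_axenisation_network(tab, "green_algae")
#' method_nodes(net)
build_axenisation_network <- function(table, division = NULL) {
  stopifnot(inherits(table, "master_table"))
  if (!is.null(division)) table <- filter_division(table, division)
  if (nrow(table) == 0) {
    abort(paste0("no records", if (!is.null(division))
      paste0(" for division '", division, "'") else ""),
      class = "axenet_validation_error")
  }
  sink <- incubation_code()
  edges <- purrr::map_dfr(table$methods, function(m) {
    path <- c(m, sink)
    tibble(from = path[-length(path)], to = path[-1])
  })
  tallied <- edges %>% count(.data$from, .data$to, name = "weight")
  nodes <- sort(unique(unlist(table$methods)))
  g <- igraph::graph_from_data_frame(tallied, directed = TRUE,
                                     vertices = c(nodes, sink))
  vocab <- method_vocabulary()
  igraph::V(g)$category <- c(vocab$category[match(nodes, vocab$code)],
                             "Sink")
  structure(list(division = division %||% "all", graph = g,
                 n_records = nrow(table),
                 n_publications = n_distinct(table$publication_id)),
            class = "workflow_network")
}

#' @export
print.workflow_network <- function(x, ...) {
  cat("<workflow_network> division=", x$division, ": ",
      length(method_nodes(x)), " method nodes (+INCB), ",
      igraph::ecount(x$graph), " distinct transitions, ",
      x$n_records, " records\n", sep = "")
  invisible(x)
}

#' Method nodes of a workflow network (excluding the incubation sink)
#' @param net A `workflow_network`.
#' @return Character vector of method codes present in the network.
#' @export
method_nodes <- function(net) {
  stopifnot(inherits(net, "workflow_network"))
  setdiff(igraph::V(net$graph)$name, incubation_code())
}

# The directed method-only graph (INCB removed); used by metrics.
method_graph <- function(net) {
  igraph::delete_vertices(net$graph, incubation_code())
}

#' Undirected projection of a workflow network
#'
#' Drops the incubation sink, collapses each directed pair u->v / v->u into
#' one undirected edge with summed weight, and optionally keeps self-loops.
#' Community detection and clique analysis operate on this view.
#'
#' @param net A `workflow_network` (or a directed igraph graph).
#' @param keep_loops Keep self-loop edges? Default `FALSE`.
#' @return An undirected weighted igraph graph.
#' @export
to_undirected <- function(net, keep_loops = FALSE) {
  g <- if (inherits(net, "workflow_network")) method_graph(net) else net
  und <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "sum",
                                                     "ignore"))
  if (!keep_loops) und <- igraph::simplify(und, remove.multiple = FALSE,
                                           remove.loops = TRUE)
  und
}

#' Build the verification-method co-usage network
#'
#' Verification methods are tallied at publication level: a publication using
#' methods \{a, b, c\} to check axenicity contributes each unordered pair once.
#' Group totals count publications using at least one method of the group
#' (microscopy, counting, sequencing, physiology).
#'
#' @param table A `master_table`.
#' @return A `verification_network`: list with `graph` (undirected weighted
#'   igraph), `usage` (tibble: `code`, `n_publications`), `group_totals`
#'   (tibble: `group`, `n_publications`) and `method_counts` (publications by
#'   number of distinct verification methods used).
#' @export
build_verification_network <- function(table) {
  stopifnot(inherits(table, "master_table"))
  vocab <- verification_vocabulary()
  per_pub <- as_tibble(table) %>%
    select("publication_id", "verification") %>%
    group_by(.data$publication_id) %>%
    summarise(codes = list(sort(unique(unlist(.data$verification)))),
              .groups = "drop")
  unknown <- setdiff(unlist(per_pub$codes), vocab$code)
  if (length(unknown) > 0) {
    abort(paste0("unknown verification code(s): ",
                 paste(unknown, collapse = ", ")),
          class = "axenet_validation_error")
  }
  usage <- tibble(code = unlist(per_pub$codes)) %>%
    count(.data$code, name = "n_publications") %>%
    arrange(.data$code)
  group_totals <- per_pub %>%
    tidyr::unnest_longer("codes", values_to = "code") %>%
    left_join(vocab, by = "code") %>%
    distinct(.data$publication_id, .data$group) %>%
    count(.data$group, name = "n_publications") %>%
    arrange(.data$group)
  method_counts <- per_pub %>%
    mutate(n_methods = lengths(.data$codes)) %>%
    count(.data$n_methods, name = "n_publications") %>%
    arrange(.data$n_methods)
  pairs <- purrr::map_dfr(per_pub$codes, function(cs) {
    if (length(cs) < 2) return(tibble(a = character(0), b = character(0)))
    cb <- combn(cs, 2)
    tibble(a = cb[1, ], b = cb[2, ])
  })
  tallied <- pairs %>% count(.data$a, .data$b, name = "weight")
  g <- igraph::graph_from_data_frame(
    tallied, directed = FALSE,
    vertices = sort(unique(unlist(per_pub$codes))))
  structure(list(graph = g, usage = usage, group_totals = group_totals,
                 method_counts = method_counts),
            class = "verification_network")
}

#' Export a network as GraphML, DOT or a CSV edge list
#'
#' @param net A `workflow_network`, `verification_network` or igraph graph.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"dot"`, `"edgelist_csv"`.
#' @param node_attrs Optional tibble (`code`, then attribute columns, e.g.
#'   success rates or community ids) copied onto matching vertices first.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("graphml", "dot", "edgelist_csv"),
                           node_attrs = NULL) {
  format <- match.arg(format)
  g <- if (igraph::is_igraph(net)) net else net$graph
  if (!is.null(node_attrs)) {
    ix <- match(igraph::V(g)$name, node_attrs$code)
    for (col in setdiff(names(node_attrs), "code")) {
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][ix])
    }
  }
  if (format == "edgelist_csv") {
    el <- igraph::as_data_frame(g, what = "edges")
    readr::write_csv(as_tibble(el), path, progress = FALSE)
  } else {
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}
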