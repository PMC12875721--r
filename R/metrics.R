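# Descriptive network statistics under the conventions of the source
# literature: edge density counts distinct realised connections against the
# theoretical maximum *including* self-loops (n^2 directed, n(n+1)/2
# undirected); degree is in+out connections per node with a loop adding one
# to each direction; modularity is Newman-Girvan Q on the undirected
# weighted loop-free projection.

as_metric_graph <- function(x) {
  if (inherits(x, "workflow_network")) return(method_graph(x))
  if (igraph::is_igraph(x)) return(x)
  abort("expected a workflow_network or an igraph graph",
        class = "axenet_validation_error")
}

#' Edge density including self-loops
#'
#' Distinct realised connections (edge presence, not weight) divided by the
#' theoretical maximum number of connections between the nodes, loops
#' included: `n^2` under the directed convention, `n(n+1)/2` under the
#' undirected one. For a `workflow_network` the incubation sink is excluded.
#'
#' @param x A `workflow_network` or igraph graph.
#' @param subset Optional character vector of node names: density of the
#'   induced subgraph (e.g. one cluster).
#' @param convention `"directed"` (default) or `"undirected"`.
#' @return Density in `[0, 1]`.
#' @export
#' @examples
#' g <- igraph::graph_from_literal(A -+ B, B -+ C, C -+ A, A -+ A)
#' edge_density_loops(g)  # 4/9
edge_density_loops <- function(x, subset = NULL,
                               convention = c("directed", "undirected")) {
  convention <- match.arg(convention)
  g <- as_metric_graph(x)
  if (!is.null(subset)) {
    if (length(subset) == 0) {
      abort("empty node subset", class = "axenet_validation_error")
    }
    missing <- setdiff(subset, igraph::V(g)$name)
    if (length(missing) > 0) {
      abort(paste0("subset node(s) not in graph: ",
                   paste(missing, collapse = ", ")),
            class = "axenet_validation_error")
    }
    g <- igraph::induced_subgraph(g, subset)
  }
  n <- igraph::vcount(g)
  if (n == 0) abort("graph has no nodes", class = "axenet_validation_error")
  if (convention == "undirected" && igraph::is_directed(g)) {
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  # presence only: collapse parallel edges, keep loops
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
  n_edges <- igraph::ecount(g)
  max_edges <- if (convention == "directed") n^2 else n * (n + 1) / 2
  n_edges / max_edges
}

#' Per-node degrees and their median
#'
#' Degree counts distinct incoming plus outgoing connections of each node; a
#' self-loop contributes one to each direction. For whole workflow networks
#' the incubation hub participates by default (`include_sink = TRUE`), so a
#' network with an odd number of methods can have a half-integer median;
#' node counts and density never include the sink.
#'
#' @param x A `workflow_network` or igraph graph.
#' @param subset Optional node-name subset: degrees within the induced
#'   subgraph (the sink is not added to subsets).
#' @param include_sink Keep the `INCB` hub when `x` is a whole
#'   `workflow_network`? Default `TRUE`.
#' @return List with `degrees` (named integer vector over method nodes) and
#'   `median`.
#' @export
degree_stats <- function(x, subset = NULL, include_sink = TRUE) {
  if (inherits(x, "workflow_network")) {
    g <- if (include_sink && is.null(subset)) x$graph else method_graph(x)
  } else {
    g <- as_metric_graph(x)
  }
  if (!is.null(subset)) {
    missing <- setdiff(subset, igraph::V(g)$name)
    if (length(missing) > 0) {
      abort(paste0("subset node(s) not in graph: ",
                   paste(missing, collapse = ", ")),
            class = "axenet_validation_error")
    }
    g <- igraph::induced_subgraph(g, subset)
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
  deg <- igraph::degree(g, mode = "all", loops = TRUE)
  list(degrees = deg, median = unname(median(deg)))
}

#' Newman-Girvan modularity of a partition
#'
#' Computes `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` where `e_c` is the total
#' intra-community edge weight, `d_c` the summed strength of community `c`
#' and `m` the total edge weight. Implemented directly from the edge list;
#' `igraph::modularity()` serves as an independent cross-check in the test
#' suite, not as the implementation.
#'
#' @param graph Undirected igraph graph (weights taken from the `weight`
#'   edge attribute unless `weighted = FALSE`); self-loops should have been
#'   removed beforehand (see [to_undirected()]).
#' @param membership Community ids: either a vector aligned with
#'   `V(graph)`, or a named vector covering every node name.
#' @param weighted Use edge weights? Default `TRUE`.
#' @return Modularity Q in `[-0.5, 1]`; `0` for an edgeless graph by
#'   convention.
#' @export
modularity_q <- function(graph, membership, weighted = TRUE) {
  stopifnot(igraph::is_igraph(graph), !igraph::is_directed(graph))
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
  if (!is.null(names(membership))) {
    missing <- setdiff(nodes, names(membership))
    if (length(missing) > 0) {
      abort(paste0("node(s) missing from partition: ",
                   paste(missing, collapse = ", ")),
            class = "axenet_validation_error")
    }
    membership <- membership[nodes]
  } else if (length(membership) != length(nodes)) {
    abort("membership length does not match node count",
          class = "axenet_validation_error")
  }
  el <- igraph::as_data_frame(graph, what = "edges")
  w <- if (weighted && !is.null(el$weight)) el$weight else
    rep(1, nrow(el))
  m <- sum(w)
  if (m == 0) return(0)
  memb <- setNames(as.vector(membership), nodes)
  # strengths d_i (loops, if present, add 2x their weight)
  d <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(w)) {
    d[el$from[i]] <- d[el$from[i]] + w[i]
    d[el$to[i]] <- d[el$to[i]] + w[i]
  }
  intra <- memb[el$from] == memb[el$to]
  e_c <- tapply(w[intra], memb[el$from][intra], sum)
  d_c <- tapply(d, memb, sum)
  q <- sum(e_c) / m - sum((d_c / (2 * m))^2)
  unname(q)
}

#' Descriptive metrics report for a workflow network
#'
#' @param net A `workflow_network`.
#' @param partition Optional `axenet_partition` for the modularity entry.
#' @param convention Density convention, see [edge_density_loops()].
#' @param weighted Weighted modularity? Default `TRUE`.
#' @return Tibble row: `division`, `n_nodes`, `n_edges_actual`, `density`,
#'   `median_degree`, `modularity_Q` (NA without a partition), `convention`.
#' @export
metrics_report <- function(net, partition = NULL,
                           convention = c("directed", "undirected"),
                           weighted = TRUE) {
  convention <- match.arg(convention)
  g <- igraph::simplify(method_graph(net), remove.multiple = TRUE,
                        remove.loops = FALSE)
  q <- NA_real_
  if (!is.null(partition)) {
    q <- modularity_q(to_undirected(net), partition$assignment,
                      weighted = weighted)
  }
  tibble(division = net$division,
         n_nodes = length(method_nodes(net)),
         n_edges_actual = igraph::ecount(g),
         density = edge_density_loops(net, convention = convention),
         median_degree = degree_stats(net)$median,
         modularity_Q = q,
         convention = convention)
}
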