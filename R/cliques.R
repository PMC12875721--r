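# Maximal clique enumeration with the Bron-Kerbosch pivoting algorithm.
# Cliques are an unweighted concept: they are computed on the simple
# undirected projection, ignoring self-loops and the incubation sink. A
# clique of methods is a set all used in immediate succession with one
# another somewhere in the corpus.

#' Enumerate all maximal cliques
#'
#' Bron-Kerbosch with greedy pivoting (the pivot maximises the number of
#' candidate neighbours, pruning its neighbourhood from the branching set).
#' Isolated vertices are returned as singleton cliques.
#'
#' @param graph An igraph graph or `workflow_network` (projected to a simple
#'   undirected graph first).
#' @return List of character vectors (sorted member names), ordered by
#'   decreasing size then lexicographically.
#' @export
#' @examples
#' g <- igraph::graph_from_literal(A - B, B - C, C - D)
#' maximal_cliques_bk(g)  # {A,B}, {B,C}, {C,D}
maximal_cliques_bk <- function(graph) {
  if (inherits(graph, "workflow_network")) graph <- to_undirected(graph)
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) {
    graph <- igraph::as_undirected(graph, mode = "collapse")
  }
  g <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (n == 0) return(list())
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                function(v) sort(as.integer(v)))
  out <- vector("list", 64L); n_out <- 0L
  emit <- function(r) {
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- r
  }
  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      emit(sort(r))
      return(invisible())
    }
    # pivot u from P union X with most neighbours in P
    px <- c(p, x)
    deg_in_p <- vapply(px, function(u) length(intersect(adj[[u]], p)), 0L)
    u <- px[which.max(deg_in_p)]
    for (v in setdiff(p, adj[[u]])) {
      nv <- adj[[v]]
      bk(c(r, v), intersect(p, nv), intersect(x, nv))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
    invisible()
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques <- lapply(out[seq_len(n_out)], function(ix) sort(nodes[ix]))
  ord <- order(-lengths(cliques), vapply(cliques, paste, "", collapse = " "))
  cliques[ord]
}

#' Largest cliques within each community
#'
#' For every community of a partition, enumerates maximal cliques of the
#' induced subgraph and reports all cliques of maximum size (co-maximal
#' cliques are all listed, ranked lexicographically).
#'
#' @param graph Undirected graph (or `workflow_network`).
#' @param partition An `axenet_partition` (or named membership vector) over
#'   the graph's nodes.
#' @return Tibble: `cluster`, `clique_rank`, `size`, `members` (list
#'   column), `members_str`.
#' @export
largest_cliques_in_cluster <- function(graph, partition) {
  if (inherits(graph, "workflow_network")) graph <- to_undirected(graph)
  memb <- if (inherits(partition, "axenet_partition"))
    partition$assignment else partition
  nodes <- igraph::V(graph)$name
  missing <- setdiff(nodes, names(memb))
  if (length(missing) > 0) {
    abort(paste0("node(s) missing from partition: ",
                 paste(missing, collapse = ", ")),
          class = "axenet_validation_error")
  }
  purrr::map_dfr(sort(unique(memb)), function(c_id) {
    sub_nodes <- names(memb)[memb == c_id]
    sub <- igraph::induced_subgraph(graph, intersect(nodes, sub_nodes))
    cl <- maximal_cliques_bk(sub)
    if (length(cl) == 0) {
      return(tibble(cluster = integer(0), clique_rank = integer(0),
                    size = integer(0), members = list(),
                    members_str = character(0)))
    }
    top <- cl[lengths(cl) == max(lengths(cl))]
    top <- top[order(vapply(top, paste, "", collapse = " "))]
    tibble(cluster = c_id, clique_rank = seq_along(top),
           size = lengths(top), members = top,
           members_str = vapply(top, paste, "", collapse = ", "))
  })
}
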