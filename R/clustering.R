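# Community detection by modularity maximisation. Networks in this domain
# are small (the largest division network has 19 method nodes), so the
# default is a globally exact branch-and-bound search per connected
# component; larger components fall back to greedy agglomerative merging.

#' Modularity-maximising partition of an undirected network
#'
#' Connected components are partitioned independently (a community never
#' gains from spanning components). Components with at most `max_exact_n`
#' nodes are solved exactly by branch and bound over all set partitions,
#' pruning with an upper bound on the attainable modularity gain; larger
#' components use greedy agglomerative merging (merge the pair with best
#' positive delta-Q until none remains). Ties between equal-Q optima are
#' broken deterministically: nodes are examined in decreasing-strength
#' order and the first optimum met is kept; community ids are then
#' canonicalised by first appearance in vertex order, so the result is
#' independent of node insertion order.
#'
#' @param graph Undirected igraph graph; self-loops are ignored for
#'   clustering. Typically [to_undirected()] of a workflow network.
#' @param max_exact_n Largest component size solved exactly (default 20).
#' @param weighted Use edge weights? Default `TRUE`.
#' @return An `axenet_partition`: list with `assignment` (named integer
#'   vector, contiguous ids from 1), `Q`, and `method` (`"exact"`,
#'   `"greedy"` or `"mixed"`).
#' @export
#' @examples
#' g <- igraph::graph_from_literal(A - B, B - C, C - A, C - D, D - E, E - F,
#'                                 F - D)
#' optimal_partition(g)
optimal_partition <- function(graph, max_exact_n = 20, weighted = TRUE) {
  stopifnot(igraph::is_igraph(graph), !igraph::is_directed(graph))
  g <- igraph::simplify(graph, remove.multiple = FALSE, remove.loops = TRUE)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- nodes
  }
  n <- length(nodes)
  if (n == 0) abort("graph has no nodes", class = "axenet_validation_error")
  if (is.null(igraph::E(g)$weight) || !weighted) {
    igraph::E(g)$weight <- 1
  }
  m <- sum(igraph::E(g)$weight)
  if (m == 0) {
    # edgeless: singletons, Q = 0 by convention
    assignment <- setNames(seq_len(n), nodes)
    return(structure(list(assignment = assignment, Q = 0,
                          method = "exact"),
                     class = "axenet_partition"))
  }
  strength <- igraph::strength(g, weights = igraph::E(g)$weight)
  comp <- igraph::components(g)
  assignment <- setNames(integer(n), nodes)
  offset <- 0L
  methods_used <- character(0)
  for (ci in seq_len(comp$no)) {
    members <- nodes[comp$membership == ci]
    if (length(members) == 1) {
      assignment[members] <- offset + 1L
      offset <- offset + 1L
      methods_used <- c(methods_used, "exact")
      next
    }
    sub <- igraph::induced_subgraph(g, members)
    if (length(members) <= max_exact_n) {
      memb <- exact_component_partition(sub, m, strength[members])
      methods_used <- c(methods_used, "exact")
    } else {
      memb <- greedy_component_partition(sub, m, strength[members])
      methods_used <- c(methods_used, "greedy")
    }
    assignment[names(memb)] <- memb + offset
    offset <- offset + max(memb)
  }
  assignment <- canonicalise_ids(assignment)
  q <- modularity_q(g, assignment, weighted = TRUE)
  method <- if (all(methods_used == "exact")) "exact"
            else if (all(methods_used == "greedy")) "greedy" else "mixed"
  structure(list(assignment = assignment, Q = q, method = method),
            class = "axenet_partition")
}

#' @export
print.axenet_partition <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat("<axenet_partition> ", k, " communities over ",
      length(x$assignment), " nodes, Q = ", format(round(x$Q, 4)),
      " (", x$method, ")\n", sep = "")
  for (c_id in sort(unique(x$assignment))) {
    cat("  [", c_id, "] ",
        paste(names(x$assignment)[x$assignment == c_id], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Relabel community ids 1..k by first appearance in the vector's order.
canonicalise_ids <- function(assignment) {
  ids <- unique(assignment)
  setNames(match(assignment, ids), names(assignment))
}

# Exact search within one component; m is the *global* total edge weight,
# so component optima combine into the global optimum.
exact_component_partition <- function(sub, m, strength) {
  members <- igraph::V(sub)$name
  ord <- order(-strength[members], seq_along(members))
  ordered <- members[ord]
  nb <- length(ordered)
  W <- matrix(0, nb, nb, dimnames = list(ordered, ordered))
  el <- igraph::as_data_frame(sub, what = "edges")
  for (i in seq_len(nrow(el))) {
    W[el$from[i], el$to[i]] <- W[el$from[i], el$to[i]] + el$weight[i]
    W[el$to[i], el$from[i]] <- W[el$to[i], el$from[i]] + el$weight[i]
  }
  k <- strength[ordered]
  B <- W - outer(k, k) / (2 * m)
  diag(B) <- 0
  res <- bb_max_pair_sum(B)
  setNames(res$membership, ordered)[members]
}

# Greedy agglomerative merging (CNM-style) within one component.
greedy_component_partition <- function(sub, m, strength) {
  members <- igraph::V(sub)$name
  nb <- length(members)
  E_mat <- matrix(0, nb, nb, dimnames = list(members, members))
  el <- igraph::as_data_frame(sub, what = "edges")
  for (i in seq_len(nrow(el))) {
    E_mat[el$from[i], el$to[i]] <- E_mat[el$from[i], el$to[i]] + el$weight[i]
    E_mat[el$to[i], el$from[i]] <- E_mat[el$to[i], el$from[i]] + el$weight[i]
  }
  comm <- as.list(seq_len(nb))          # communities as member-index sets
  d_c <- as.numeric(strength[members])  # community strength sums
  e_cd <- E_mat                         # inter-community weights
  repeat {
    k <- length(comm)
    if (k == 1) break
    best <- c(NA, NA); best_dq <- 0
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        if (e_cd[a, b] <= 0) next
        dq <- e_cd[a, b] / m - 2 * (d_c[a] / (2 * m)) * (d_c[b] / (2 * m))
        if (dq > best_dq + 1e-12) {
          best_dq <- dq; best <- c(a, b)
        }
      }
    }
    if (is.na(best[1])) break
    a <- best[1]; b <- best[2]
    comm[[a]] <- c(comm[[a]], comm[[b]]); comm[[b]] <- NULL
    d_c[a] <- d_c[a] + d_c[b]
    e_cd[a, ] <- e_cd[a, ] + e_cd[b, ]
    e_cd[, a] <- e_cd[, a] + e_cd[, b]
    keep <- setdiff(seq_len(k), b)
    d_c <- d_c[keep]; e_cd <- e_cd[keep, keep, drop = FALSE]
  }
  memb <- integer(nb)
  for (ci in seq_along(comm)) memb[comm[[ci]]] <- ci
  setNames(memb, members)
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two partitions of the same node set, computed from the
#' pair-counting contingency formula; 1 for identical partitions up to
#' relabelling, about 0 for independent ones.
#'
#' @param a,b `axenet_partition` objects or named membership vectors over
#'   the same node set.
#' @return ARI in `[-1, 1]`.
#' @export
compare_partitions <- function(a, b) {
  ma <- if (inherits(a, "axenet_partition")) a$assignment else a
  mb <- if (inherits(b, "axenet_partition")) b$assignment else b
  if (is.null(names(ma)) || is.null(names(mb))) {
    abort("partitions must be named membership vectors",
          class = "axenet_validation_error")
  }
  if (!setequal(names(ma), names(mb))) {
    abort("partitions cover different node sets",
          class = "axenet_validation_error")
  }
  mb <- mb[names(ma)]
  tab <- table(ma, mb)
  nch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(nch2(tab))
  sum_a <- sum(nch2(rowSums(tab)))
  sum_b <- sum(nch2(colSums(tab)))
  n_pairs <- nch2(length(ma))
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions degenerate
  (sum_ij - expected) / (max_index - expected)
}
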