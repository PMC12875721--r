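# Independent oracles used across the suite. These deliberately use naive
# enumeration / direct formulas so they share no code with the package
# implementations they check.

# All set partitions of n elements as membership vectors (restricted
# growth strings); Bell(8) = 4140, fine for n <= 8.
all_set_partitions <- function(n) {
  out <- list()
  recur <- function(memb, next_id) {
    t <- length(memb)
    if (t == n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (c_id in seq_len(next_id)) {
      recur(c(memb, c_id), max(next_id, c_id + 1))
    }
  }
  recur(integer(0), 1L)
  out
}

# Brute-force maximum modularity over every set partition.
brute_force_max_q <- function(graph, weighted = TRUE) {
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(igraph::vcount(graph)))
    igraph::V(graph)$name <- nodes
  }
  parts <- all_set_partitions(length(nodes))
  qs <- vapply(parts, function(p)
    modularity_q(graph, stats::setNames(p, nodes), weighted = weighted), 0)
  max(qs)
}

# Brute-force maximal cliques: test every vertex subset for pairwise
# adjacency, then discard non-maximal ones.
brute_force_maximal_cliques <- function(graph) {
  g <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  cliques <- list()
  for (mask in seq_len(2^n) - 1L) {
    ix <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(ix) == 0) next
    ok <- TRUE
    if (length(ix) > 1) {
      pr <- utils::combn(ix, 2)
      ok <- all(adj[cbind(pr[1, ], pr[2, ])])
    }
    if (ok) cliques[[length(cliques) + 1]] <- ix
  }
  maximal <- Filter(function(cl) {
    !any(vapply(cliques, function(other)
      length(other) > length(cl) && all(cl %in% other), TRUE))
  }, cliques)
  sets <- lapply(maximal, function(ix) sort(nodes[ix]))
  sets[order(-lengths(sets), vapply(sets, paste, "", collapse = " "))]
}

# Adjusted Rand index by explicit O(n^2) pair counting (same-same /
# same-diff tallies), independent of the contingency-table implementation.
ari_pair_count <- function(a, b) {
  b <- b[names(a)]
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  np <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / np
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# Seeded Erdos-Renyi graph with optional integer weights.
random_test_graph <- function(n, p, seed, weighted = TRUE) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- LETTERS[seq_len(n)]
  if (weighted && igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- sample(1:5, igraph::ecount(g), replace = TRUE)
  }
  g
}

# A record row for handcrafted master tables.
make_record <- function(publication_id, species, methods,
                        outcome = "success", division = "diatoms",
                        year = 2020L, countries = "Ireland",
                        habitat = "marine", media = "f/2",
                        verification = character(0),
                        antibiotics = NULL,
                        rater1 = "yes|yes|yes|multiple|yes",
                        rater2 = "yes|yes|yes|multiple|yes",
                        rater3 = "yes|yes|yes|multiple|yes") {
  if (is.null(antibiotics)) {
    antibiotics <- tibble::tibble(class = character(0),
                                  compound = character(0),
                                  concentration = numeric(0))
  }
  tibble::tibble(publication_id = publication_id, year = year,
                 countries = list(countries), division = division,
                 species = species, habitat = habitat, media = media,
                 methods = list(methods), outcome = outcome,
                 verification = list(verification),
                 antibiotics = list(antibiotics),
                 rater1 = rater1, rater2 = rater2, rater3 = rater3)
}

make_table <- function(...) {
  as_master_table(dplyr::bind_rows(...))
}

# Same brute force as brute_force_max_q but evaluating Q via the modularity
# matrix B = W - k k^T / 2m (fast enough for 100 graphs at n = 8); shares
# no code with either modularity_q or the branch-and-bound search.
brute_force_max_q_fast <- function(graph, weighted = TRUE) {
  g <- igraph::simplify(graph, remove.multiple = FALSE, remove.loops = TRUE)
  n <- igraph::vcount(g)
  W <- igraph::as_adjacency_matrix(
    g, sparse = FALSE,
    attr = if (weighted && !is.null(igraph::E(g)$weight)) "weight" else NULL)
  m <- sum(W) / 2
  if (m == 0) return(0)
  k <- rowSums(W)
  B <- W - outer(k, k) / (2 * m)
  best <- -Inf
  for (p in all_set_partitions(n)) {
    same <- outer(p, p, "==")
    q <- sum(B[same]) / (2 * m)
    if (q > best) best <- q
  }
  best
}
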