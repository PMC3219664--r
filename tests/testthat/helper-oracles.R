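# Independent brute-force oracles used to validate the production graph
# statistics. These deliberately use naive enumeration, not the algorithms
# under test.

# exhaustive depth-first enumeration of simple paths between every pair;
# aggregates (target, length) visit counts rather than storing paths, and
# returns shortest-path length and geodesic-count matrices (NA when
# unreachable)
oracle_apsp <- function(graph) {
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  len <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  cnt <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  diag(len) <- 0; diag(cnt) <- 1
  for (s in seq_len(n)) {
    hits <- matrix(0, n, n)    # hits[t, d]: simple paths s -> t of length d
    walk <- function(v, depth, visited) {
      for (u in adj[[v]]) {
        if (visited[u]) next
        hits[u, depth + 1L] <<- hits[u, depth + 1L] + 1
        vis2 <- visited; vis2[u] <- TRUE
        walk(u, depth + 1L, vis2)
      }
    }
    visited <- rep(FALSE, n); visited[s] <- TRUE
    walk(s, 0L, visited)
    for (t in seq_len(n)) {
      if (t == s) next
      ds <- which(hits[t, ] > 0)
      if (length(ds)) {
        len[s, t] <- min(ds)
        cnt[s, t] <- hits[t, min(ds)]
      }
    }
  }
  list(lengths = len, counts = cnt)
}

# transitivity by enumeration over all node triples
oracle_transitivity <- function(graph) {
  n <- igraph::vcount(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  tri <- 0L
  for (i in seq_len(n - 2L))
    for (j in seq.int(i + 1L, n - 1L))
      for (k in seq.int(j + 1L, n))
        if (A[i, j] && A[j, k] && A[i, k]) tri <- tri + 1L
  triples <- sum(choose(rowSums(A), 2L))
  3 * tri / triples
}

# random connected graph with n nodes (named), for property suites
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) >= n - 1L) break
  }
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# single-person history builder: named symptoms x days matrix of zeros
empty_history <- function(symptoms, days) {
  matrix(0L, length(symptoms), days,
         dimnames = list(symptoms, seq_len(days)))
}
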