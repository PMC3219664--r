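#' Giant component of a graph
#'
#' @param graph an `igraph` graph.
#' @return list with `graph` (induced subgraph of the largest connected
#'   component; ties broken by the lexicographically smallest member label)
#'   and `fraction` (its share of all nodes).
#' @export
giant_component <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  comp <- igraph::components(graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    nm <- igraph::V(graph)$name
    if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
    mins <- vapply(best, function(b) min(nm[comp$membership == b]), "")
    best <- best[order(mins)][1L]
  }
  sub <- igraph::induced_subgraph(graph, which(comp$membership == best))
  list(graph = sub, fraction = max(comp$csize) / igraph::vcount(graph))
}

#' Global clustering coefficient (transitivity)
#'
#' Defined as 3 times the number of triangles divided by the number of paths
#' of length 2 (equivalently, connected triples).
#'
#' @param graph an `igraph` graph.
#' @return transitivity in `[0, 1]`; errors if the graph has no paths of
#'   length 2 (the ratio is undefined, not zero).
#' @export
transitivity_global <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  deg <- igraph::degree(graph)
  if (sum(choose(deg, 2L)) == 0)
    stop("transitivity undefined: graph has no paths of length 2")
  igraph::transitivity(graph, type = "global")
}

#' All-pairs shortest path lengths and geodesic counts
#'
#' Path lengths come from breadth-first search; the number of distinct
#' shortest paths (geodesics) per pair is accumulated with the standard BFS
#' path-count recursion: sigma(s,v) = sum of sigma(s,u) over predecessors u of
#' v on shortest paths.
#'
#' @param graph an `igraph` graph.
#' @return list with `lengths` and `counts`, both symmetric matrices with the
#'   vertex names as dimnames. Unreachable pairs are `NA` in both (never a
#'   numeric infinity); diagonals are 0 and 1 respectively.
#' @export
all_pairs_shortest_paths <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  d <- igraph::distances(graph, weights = NA)
  d[is.infinite(d)] <- NA_real_
  adj <- igraph::as_adj_list(graph, mode = "all")
  adj <- lapply(adj, as.integer)
  sig <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (s in seq_len(n)) {
    dist_s <- d[s, ]
    sigma <- rep(NA_real_, n)
    sigma[s] <- 1
    reach <- which(!is.na(dist_s))
    ord <- reach[order(dist_s[reach])]
    for (v in ord) {
      if (v == s) next
      preds <- adj[[v]][!is.na(dist_s[adj[[v]]]) &
                          dist_s[adj[[v]]] == dist_s[v] - 1]
      sigma[v] <- sum(sigma[preds])
    }
    sig[s, ] <- sigma
  }
  list(lengths = d, counts = sig)
}

#' Summary statistics of a connected symptom graph
#'
#' Bundles the global properties used to characterise a giant component:
#' node and edge counts, mean degree, density, transitivity, average shortest
#' path length over unordered pairs, and the mean number of distinct shortest
#' paths (geodesics) per unordered pair.
#'
#' @param graph a connected `igraph` graph (apply [giant_component()] first
#'   if necessary).
#' @return object of class `network_summary`.
#' @export
summarize_network <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) < 2L) stop("need at least 2 nodes")
  if (!igraph::is_connected(graph))
    stop("graph is disconnected; restrict to a component first (see giant_component)")
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  ap <- all_pairs_shortest_paths(graph)
  ut <- upper.tri(ap$lengths)
  structure(list(
    n = n, m = m,
    mean_degree = 2 * m / n,
    density = m / choose(n, 2L),
    C = transitivity_global(graph),
    L = mean(ap$lengths[ut]),
    mean_geodesic_count = mean(ap$counts[ut]),
    degree_sequence = igraph::degree(graph)
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, digits = 3, ...) {
  cat("Symptom graph summary\n")
  cat(sprintf("  nodes: %d   edges: %d\n", x$n, x$m))
  cat(sprintf("  mean degree <k>: %s   density p: %s\n",
              format(x$mean_degree, digits = digits),
              format(x$density, digits = digits)))
  cat(sprintf("  clustering C (transitivity): %s\n", format(x$C, digits = digits)))
  cat(sprintf("  average shortest path length L: %s\n", format(x$L, digits = digits)))
  cat(sprintf("  mean geodesic count per pair: %s\n",
              format(x$mean_geodesic_count, digits = digits)))
  invisible(x)
}

#' Random-graph expectations for clustering and path length
#'
#' Closed-form expectations for an Erdos-Renyi random graph with `n` nodes
#' and `m` edges: `C_rnd = <k>/n` (the edge probability) and
#' `L_rnd = (ln n - gamma)/ln <k> + 1/2` with `gamma` the Euler-Mascheroni
#' constant. These are the size-matched baselines entering the
#' small-world-ness index.
#'
#' @param n,m node and edge counts.
#' @return object of class `er_expectation` with fields `C_rnd`, `L_rnd`,
#'   `n`, `m`.
#' @examples
#' er_expectations(208, 1949)  # C_rnd ~ 0.09, L_rnd ~ 2.12
#' @export
er_expectations <- function(n, m) {
  stopifnot(n >= 2, m >= 0)
  k <- 2 * m / n
  if (k <= 1)
    stop("mean degree <= 1: random-graph closed forms are invalid here")
  gamma <- -digamma(1)
  structure(list(
    C_rnd = k / n,
    L_rnd = (log(n) - gamma) / log(k) + 0.5,
    n = n, m = m, mean_degree = k
  ), class = "er_expectation")
}

#' @export
print.er_expectation <- function(x, digits = 3, ...) {
  cat(sprintf("Random graph G(n=%d, m=%d): C_rnd = %s, L_rnd = %s\n",
              x$n, x$m, format(x$C_rnd, digits = digits),
              format(x$L_rnd, digits = digits)))
  invisible(x)
}

#' Sample random graphs and their small-world statistics
#'
#' Draws `reps` uniform G(n, m) graphs (exactly `m` edges), restricts each to
#' its giant component, and records clustering, average path length, density
#' and the small-world-ness index (with closed-form baselines at the sampled
#' `n`, `m`).
#'
#' @param n,m node and edge counts of each sample.
#' @param reps number of replicates.
#' @param seed integer seed; fixed seed gives identical output.
#' @return data frame with columns `C`, `L`, `swi`, `density`, `n_gc`.
#' @export
sample_er_graphs <- function(n, m, reps, seed = 1L) {
  stopifnot(reps >= 1, n >= 2)
  if (m > choose(n, 2L)) stop("m exceeds the maximum n(n-1)/2")
  set.seed(seed)
  base <- er_expectations(n, m)
  out <- vapply(seq_len(reps), function(i) {
    g <- igraph::sample_gnm(n, m)
    gc <- giant_component(g)$graph
    C <- transitivity_global(gc)
    L <- igraph::mean_distance(gc, directed = FALSE)
    c(C = C, L = L,
      swi = (C / base$C_rnd) / (L / base$L_rnd),
      density = igraph::ecount(gc) / choose(igraph::vcount(gc), 2L),
      n_gc = igraph::vcount(gc))
  }, numeric(5))
  as.data.frame(t(out))
}

#' Small-world-ness index
#'
#' `SWI = (C / C_rnd) / (L / L_rnd)`, comparing observed clustering and
#' average path length to the closed-form expectations of a random graph with
#' the same number of nodes and edges ([er_expectations()]). Values above 3
#' are conventionally taken to indicate small-world structure.
#'
#' @param C observed clustering coefficient (transitivity).
#' @param L observed average shortest path length.
#' @param n,m node and edge counts defining the random baseline.
#' @return object of class `small_world_result` with fields `swi`, `C`, `L`,
#'   `C_rnd`, `L_rnd`.
#' @examples
#' small_world_index(C = 0.68, L = 2.6, n = 208, m = 1949)  # about 6.2
#' @export
small_world_index <- function(C, L, n, m) {
  stopifnot(C >= 0, L > 0, n >= 2, m >= 1)
  base <- er_expectations(n, m)
  if (C == 0) warning("zero clustering coefficient: SWI is 0")
  swi <- (C / base$C_rnd) / (L / base$L_rnd)
  structure(list(swi = swi, C = C, L = L,
                 C_rnd = base$C_rnd, L_rnd = base$L_rnd, n = n, m = m),
            class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, digits = 3, ...) {
  cat(sprintf("SWI = %s  [C = %s vs C_rnd = %s; L = %s vs L_rnd = %s]\n",
              format(x$swi, digits = digits), format(x$C, digits = digits),
              format(x$C_rnd, digits = digits), format(x$L, digits = digits),
              format(x$L_rnd, digits = digits)))
  invisible(x)
}

#' Classify a degree distribution tail: exponential vs power law
#'
#' Computes the empirical survival function P(K > k) at the distinct observed
#' degrees and fits its logarithm linearly against k (exponential decay) and
#' against log k (power law), without binning. The model with the larger
#' coefficient of determination wins; differences below `tie_margin` are
#' reported as `"indeterminate"`. A single-scale network shows exponential
#' decay.
#'
#' @param degree_sequence integer vector of node degrees.
#' @param tie_margin minimum R-squared difference to declare a winner.
#' @return object of class `degree_tail_fit`: `classification`, and per-model
#'   `r_squared`, slopes and fitted objects.
#' @export
degree_tail_fit <- function(degree_sequence, tie_margin = 0.01) {
  ks <- sort(unique(degree_sequence))
  if (length(ks) < 2L) stop("degenerate (constant) degree sequence")
  if (length(ks) < 10L) stop("need at least 10 distinct degrees to classify a tail")
  surv <- vapply(ks, function(k) mean(degree_sequence > k), numeric(1))
  keep <- surv > 0 & ks > 0
  ks <- ks[keep]; surv <- surv[keep]
  fit_exp <- stats::lm(log(surv) ~ ks)
  fit_pow <- stats::lm(log(surv) ~ log(ks))
  r2 <- c(exponential = summary(fit_exp)$r.squared,
          `power-law` = summary(fit_pow)$r.squared)
  cls <- if (abs(diff(r2)) < tie_margin) "indeterminate" else names(which.max(r2))
  structure(list(classification = cls, r_squared = r2,
                 exponential = fit_exp, power_law = fit_pow,
                 k = ks, survival = surv),
            class = "degree_tail_fit")
}

#' @export
print.degree_tail_fit <- function(x, ...) {
  cat(sprintf("Degree tail: %s (R2 exponential = %.3f, power-law = %.3f)\n",
              x$classification, x$r_squared[["exponential"]],
              x$r_squared[["power-law"]]))
  invisible(x)
}

#' Current-flow (random-walk) betweenness centrality
#'
#' Exact random-walk betweenness: node throughput of unit electrical current
#' injected at s and extracted at t, averaged over all source-target pairs.
#' Computed from the Moore-Penrose pseudoinverse of the graph Laplacian;
#' deterministic and invariant under node relabeling.
#'
#' @param graph a connected `igraph` graph.
#' @return named numeric vector of centralities, averaged over the
#'   `(n-1)(n-2)/2` pairs not involving the node itself.
#' @seealso [mc_walk_betweenness()] for the Monte-Carlo walker estimate.
#' @export
random_walk_betweenness <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  if (n < 3L) stop("need at least 3 nodes")
  if (!igraph::is_connected(graph)) stop("graph must be connected")
  lap <- igraph::laplacian_matrix(graph, sparse = FALSE, weights = NA)
  Cinv <- MASS::ginv(lap)
  el <- igraph::as_edgelist(graph, names = FALSE)
  ei <- el[, 1L]; ej <- el[, 2L]
  bet <- numeric(n)
  for (s in seq_len(n - 1L)) {
    ps <- Cinv[, s]
    for (t in seq.int(s + 1L, n)) {
      p <- ps - Cinv[, t]
      cur <- abs(p[ei] - p[ej])
      thr <- numeric(n)
      sums <- rowsum(c(cur, cur), c(ei, ej))
      thr[as.integer(rownames(sums))] <- 0.5 * sums[, 1L]
      thr[c(s, t)] <- 0      # endpoints are not intermediaries
      bet <- bet + thr
    }
  }
  bet <- bet / ((n - 1) * (n - 2) / 2)
  names(bet) <- igraph::V(graph)$name
  bet
}

#' Monte-Carlo random-walk betweenness
#'
#' The walker formulation of random-walk betweenness: for consecutive
#' simple random walks from a source absorbed at a target, the *net* number
#' of times each edge is crossed is averaged over the walks of that pair;
#' the magnitude of that average is the walk current on the edge, and a
#' node's throughput is half the sum over its incident edges, averaged over
#' all source-target pairs (endpoints excluded). Averaging net crossings
#' (rather than raw visit counts, which over-weight high-degree nodes that
#' walks revisit idly) is what makes the estimate converge to the exact
#' current-flow measure of [random_walk_betweenness()] as the number of
#' walks grows.
#'
#' @param graph a connected `igraph` graph.
#' @param walks total number of walks (>= 1), spread evenly over all
#'   unordered node pairs (at least one walk per pair).
#' @param pairs optional list of 2-vectors of vertex names restricting the
#'   source-target pairs.
#' @param seed integer seed.
#' @param max_steps per-walk step cap (guard against pathological runs).
#' @return named numeric vector: per-node mean walk throughput.
#' @export
mc_walk_betweenness <- function(graph, walks, pairs = NULL, seed = 1L,
                                max_steps = 1e6) {
  stopifnot(igraph::is_igraph(graph), walks >= 1)
  n <- igraph::vcount(graph)
  if (n < 3L) stop("need at least 3 nodes")
  if (!igraph::is_connected(graph)) stop("graph must be connected")
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  deg <- lengths(adj)
  el <- igraph::as_edgelist(graph, names = FALSE)
  m <- nrow(el)
  eid <- matrix(0L, n, n)   # signed edge index lookup
  for (e in seq_len(m)) {
    eid[el[e, 1L], el[e, 2L]] <- e
    eid[el[e, 2L], el[e, 1L]] <- -e
  }
  if (is.null(pairs)) {
    pr <- utils::combn(n, 2L)
  } else {
    pr <- vapply(pairs, function(p) match(p, nm), integer(2))
  }
  wpp <- max(1L, as.integer(round(walks / ncol(pr))))
  set.seed(seed)
  bet <- numeric(n)
  for (pi in seq_len(ncol(pr))) {
    s <- pr[1L, pi]; t <- pr[2L, pi]
    cross <- numeric(m)
    for (w in seq_len(wpp)) {
      v <- s
      steps <- 0L
      while (v != t) {
        u <- adj[[v]][sample.int(deg[v], 1L)]
        e <- eid[v, u]
        cross[abs(e)] <- cross[abs(e)] + sign(e)
        v <- u
        steps <- steps + 1L
        if (steps > max_steps) stop("walk exceeded max_steps; graph too large?")
      }
    }
    cur <- abs(cross / wpp)
    thr <- numeric(n)
    sums <- rowsum(c(cur, cur), c(el[, 1L], el[, 2L]))
    thr[as.integer(rownames(sums))] <- 0.5 * sums[, 1L]
    thr[c(s, t)] <- 0
    bet <- bet + thr
  }
  out <- bet / ncol(pr)
  names(out) <- nm
  out
}
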