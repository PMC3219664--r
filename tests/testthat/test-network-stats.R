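test_that("giant component selects the largest component, ties by label", {
  dj <- incidence_table(data.frame(
    symptom = c(letters[1:5], LETTERS[1:3]),
    disorder = rep(c("D1", "D2"), c(5, 3))))
  g <- project_to_symptom_graph(dj)
  gc <- giant_component(g)
  expect_equal(igraph::vcount(gc$graph), 5L)
  expect_equal(gc$fraction, 5 / 8)

  fx <- mde_gad_fixture()
  gfx <- project_to_symptom_graph(fx$table)
  expect_equal(giant_component(gfx)$fraction, 1)

  # tie: two K3s, the one holding the smallest label wins
  tie <- igraph::graph_from_edgelist(
    rbind(c("b", "c"), c("c", "d"), c("b", "d"),
          c("a", "e"), c("e", "f"), c("a", "f")), directed = FALSE)
  expect_true("a" %in% igraph::V(giant_component(tie)$graph)$name)

  expect_error(giant_component(igraph::make_empty_graph(directed = FALSE)),
               "empty")
})

test_that("transitivity matches triple enumeration", {
  expect_equal(transitivity_global(igraph::make_full_graph(3)), 1)
  path3 <- igraph::make_graph(~ a - b - c)
  expect_equal(transitivity_global(path3), 0)
  # undefined without any length-2 path
  expect_error(transitivity_global(igraph::make_graph(~ a - b)),
               "undefined")

  fx <- mde_gad_fixture()
  g <- project_to_symptom_graph(fx$table)
  expect_equal(transitivity_global(g), 3 * 164 / 592, tolerance = 1e-12)
  expect_equal(transitivity_global(g), oracle_transitivity(g),
               tolerance = 1e-12)

  set.seed(31)
  for (i in 1:6) {
    gr <- random_connected_graph(sample(5:12, 1), p = runif(1, 0.3, 0.6))
    expect_equal(transitivity_global(gr), oracle_transitivity(gr),
                 tolerance = 1e-12)
  }
})

test_that("shortest path lengths and geodesic counts match exhaustive enumeration", {
  # 4-cycle: opposite corners at distance 2 with two geodesics
  c4 <- igraph::make_ring(4)
  igraph::V(c4)$name <- letters[1:4]
  ap <- all_pairs_shortest_paths(c4)
  expect_equal(ap$lengths["a", "b"], 1)
  expect_equal(ap$lengths["a", "c"], 2)
  expect_equal(ap$counts["a", "c"], 2)

  # complete graph: every pair one geodesic of length 1
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  ap5 <- all_pairs_shortest_paths(k5)
  expect_true(all(ap5$lengths[upper.tri(ap5$lengths)] == 1))
  expect_true(all(ap5$counts[upper.tri(ap5$counts)] == 1))

  # fixture: one geodesic per bridge between the disorder cores
  fx <- mde_gad_fixture()
  g <- project_to_symptom_graph(fx$table)
  ap <- all_pairs_shortest_paths(g)
  expect_equal(ap$lengths["mDep", "gAnx"], 2)
  expect_equal(ap$counts["mDep", "gAnx"], 4)
  # every core-MDE/core-GAD pair: distance 2, one geodesic per bridge
  for (m in c("mDep", "mInt", "mWei", "mRep", "mSui"))
    for (a in c("gAnx", "gEve", "gCtr", "gMus", "gIrr")) {
      expect_equal(ap$lengths[m, a], 2)
      expect_equal(ap$counts[m, a], 4)
    }

  # randomized property suite on small graphs
  set.seed(77)
  for (i in 1:12) {
    gr <- random_connected_graph(sample(4:9, 1), p = runif(1, 0.3, 0.7))
    got <- all_pairs_shortest_paths(gr)
    want <- oracle_apsp(gr)
    expect_equal(got$lengths, want$lengths)
    expect_equal(got$counts, want$counts)
  }

  # unreachable pairs are NA, not infinite
  two <- igraph::make_graph(~ a - b, c - d)
  apd <- all_pairs_shortest_paths(two)
  expect_true(is.na(apd$lengths["a", "c"]))
  expect_true(is.na(apd$counts["a", "c"]))
  expect_false(any(is.infinite(apd$lengths)))
})

test_that("network summaries satisfy their identities", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  s4 <- summarize_network(k4)
  expect_equal(s4$mean_degree, 3)
  expect_equal(s4$L, 1)
  expect_equal(s4$mean_geodesic_count, 1)

  fx <- mde_gad_fixture()
  g <- project_to_symptom_graph(fx$table)
  s <- summarize_network(g)
  expect_equal(s$L, 116 / 91, tolerance = 1e-12)
  expect_equal(s$mean_geodesic_count, 166 / 91, tolerance = 1e-12)
  expect_equal(s$mean_degree * s$n, 2 * s$m)
  expect_equal(s$density * choose(s$n, 2), s$m)

  disc <- igraph::make_graph(~ a - b, c - d)
  expect_error(summarize_network(disc), "disconnected")
})

test_that("random-graph expectations reproduce the closed forms", {
  e <- er_expectations(208, 1949)
  expect_equal(e$C_rnd, (2 * 1949 / 208) / 208, tolerance = 1e-12)
  expect_equal(e$C_rnd, 0.09, tolerance = 0.01)
  expect_equal(e$L_rnd, 2.12, tolerance = 0.005)

  # dense limit sanity: L_rnd stays near 1 for a complete graph
  e10 <- er_expectations(10, choose(10, 2))
  expect_lt(e10$L_rnd, 1.6)
  expect_equal(e10$C_rnd, 9 / 10, tolerance = 1e-12)

  expect_error(er_expectations(100, 40), "mean degree")
})

test_that("sampled G(n,m) ensembles are reproducible and match the closed forms", {
  s1 <- sample_er_graphs(60, 180, reps = 5, seed = 11)
  s2 <- sample_er_graphs(60, 180, reps = 5, seed = 11)
  expect_identical(s1, s2)
  expect_error(sample_er_graphs(10, 100, reps = 1), "exceeds")

  # closed-form agreement at a size where the asymptotics hold
  e <- er_expectations(1000, 5000)
  smp <- sample_er_graphs(1000, 5000, reps = 40, seed = 2)
  expect_lt(abs(mean(smp$L) - e$L_rnd) / e$L_rnd, 0.02)
  se_c <- stats::sd(smp$C) / sqrt(nrow(smp))
  expect_lt(abs(mean(smp$C) - e$C_rnd), 3 * se_c)
})

test_that("small-world-ness index follows its definition", {
  sw <- small_world_index(0.68, 2.6, 208, 1949)
  expect_equal(sw$swi, (0.68 / sw$C_rnd) / (2.6 / sw$L_rnd), tolerance = 1e-12)
  expect_equal(sw$swi, 6.2, tolerance = 0.05)

  # identity case: a random graph is its own baseline
  e <- er_expectations(208, 1949)
  expect_equal(small_world_index(e$C_rnd, e$L_rnd, 208, 1949)$swi, 1,
               tolerance = 1e-12)
  for (nm in list(c(50, 200), c(500, 2000))) {
    e2 <- er_expectations(nm[1], nm[2])
    expect_equal(small_world_index(e2$C_rnd, e2$L_rnd, nm[1], nm[2])$swi, 1,
                 tolerance = 1e-12)
  }

  expect_warning(sw0 <- small_world_index(0, 2, 50, 200), "zero")
  expect_equal(sw0$swi, 0)
})

test_that("degree tails classify exponential vs power-law decay", {
  set.seed(5)
  geo <- rgeom(2000, 0.15) + 1
  expect_equal(degree_tail_fit(geo)$classification, "exponential")
  par <- floor(1 / runif(2000)^(1 / 1.8))
  expect_equal(degree_tail_fit(par)$classification, "power-law")
  expect_error(degree_tail_fit(rep(4, 100)), "degenerate")
  expect_error(degree_tail_fit(rep(1:3, 50)), "distinct")
})

test_that("current-flow betweenness respects symmetry and dominance", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- letters[1:6]
  bs <- random_walk_betweenness(star)
  expect_equal(unname(which.max(bs)), 1L)
  expect_true(all(bs[1] > bs[-1]))

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  bk <- random_walk_betweenness(k4)
  expect_equal(max(bk) - min(bk), 0, tolerance = 1e-10)

  p5 <- igraph::make_graph(~ a - b - c - d - e)
  bp <- random_walk_betweenness(p5)
  expect_equal(unname(which.max(bp)), 3L)
  expect_true(bp["b"] > bp["a"] && bp["d"] > bp["e"])

  # invariant under relabeling (permutation of vertex ids)
  g <- random_connected_graph(8, 0.4)
  perm <- sample(8)
  gp <- igraph::permute(g, perm)
  b1 <- random_walk_betweenness(g)
  b2 <- random_walk_betweenness(gp)
  expect_equal(b1[igraph::V(g)$name], b2[igraph::V(g)$name],
               tolerance = 1e-10)

  expect_error(random_walk_betweenness(igraph::make_graph(~ a - b, c - d)),
               "connected")
})

test_that("the Monte-Carlo walker agrees with the exact current-flow measure", {
  # every endpoint-to-endpoint walk on a path passes the middle node, so
  # its net throughput for that pair is exactly one crossing
  p3 <- igraph::make_graph(~ a - b - c)
  mc3 <- mc_walk_betweenness(p3, walks = 300, seed = 2,
                             pairs = list(c("a", "c")))
  expect_equal(unname(mc3["b"]), 1)
  expect_equal(unname(mc3[c("a", "c")]), c(0, 0))

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  mck <- mc_walk_betweenness(k4, walks = 6000, seed = 3)
  expect_lt(max(mck) - min(mck), 0.1)

  set.seed(8)
  g <- igraph::sample_gnm(20, 45)
  while (!igraph::is_connected(g)) g <- igraph::sample_gnm(20, 45)
  igraph::V(g)$name <- letters[1:20]
  ex <- random_walk_betweenness(g)
  mc <- mc_walk_betweenness(g, walks = 19000, seed = 4)
  expect_gt(stats::cor(ex, mc, method = "spearman"), 0.9)
  # convergence: more walks tighten the agreement beyond a coarse run
  mc_coarse <- mc_walk_betweenness(g, walks = 1900, seed = 4)
  expect_gte(stats::cor(ex, mc, method = "spearman") + 0.02,
             stats::cor(ex, mc_coarse, method = "spearman"))

  # determinism under seed
  mc2 <- mc_walk_betweenness(g, walks = 500, seed = 4)
  expect_identical(mc2, mc_walk_betweenness(g, walks = 500, seed = 4))
})
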