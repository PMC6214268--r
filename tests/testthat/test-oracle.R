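test_that("atlas class counts are reproduced by enumeration", {
  expect_equal(count_directed_quad_classes(), 218)
  expect_equal(count_triad_classes(), 16)
  expect_equal(count_quad_classes(), 11)
})

test_that("brute quad census classifies canonical graphs correctly", {
  k4 <- brute_quad_census(edges_k(4))
  expect_equal(unname(k4$node_induced[, "o19"]), rep(1, 4))
  expect_equal(unname(k4$graph["K4"]), 1)
  c4 <- brute_quad_census(edges_cycle(4))
  expect_equal(unname(c4$edge_induced[, "o10"]), rep(1, 4))
  paw <- brute_quad_census(edges_paw())
  expect_equal(unname(paw$node_noninduced["b", "o14"]), 1)
  expect_error(brute_quad_census(gen_gnp(41, 0.1, seed = 1)), "too large")
})

test_that("brute census is self-consistent: orbit sums equal multiplicity times class counts", {
  # orbit multiplicity = number of nodes of the quad in that orbit
  mult <- c(4, 2, 2, 4, 2, 1, 1, 3, 1, 2, 2, 1, 3, 1, 2, 1, 4, 2, 2, 4)
  qcls <- orbcensus:::node_orbit_class()
  for (i in 1:10) {
    g <- rand_undirected(i, nmax = 15)
    ref <- brute_quad_census(g)
    tot <- colSums(ref$node_induced)
    expect_equal(unname(tot), mult * unname(ref$graph[qcls]))
  }
})

test_that("brute triad census matches trivial cases and size guard", {
  e3 <- brute_triad_census(directed_graph(matrix(integer(0), 0, 2),
                                          nodes = 1:3))
  expect_equal(unname(e3$graph["003"]), 1)
  cyc <- brute_triad_census(directed_graph(rbind(c(1, 2), c(2, 3), c(3, 1))))
  expect_equal(unname(cyc$node[, "o21"]), rep(1, 3))
  r8 <- brute_triad_census(gen_gnp(8, 0.3, seed = 4, directed = TRUE))
  expect_equal(sum(r8$graph), choose(8, 3))
  expect_error(brute_triad_census(gen_gnp(61, 0.01, seed = 1,
                                          directed = TRUE)), "too large")
})

test_that("coefficient derivation solves random instances in both directions", {
  for (level in c("node", "edge")) {
    C <- derive_quad_coefficients(level)
    for (i in 1:25) {
      g <- rand_undirected(100 + i, nmax = 14)
      ref <- brute_quad_census(g)
      ni <- if (level == "node") ref$node_induced else ref$edge_induced
      nn <- if (level == "node") ref$node_noninduced else ref$edge_noninduced
      if (nrow(ni) == 0) next
      # forward: nn = C ni; backward: back-substitution recovers ni
      expect_equal(unname(nn), unname(ni %*% t(C)))
      expect_equal(unname(orbcensus:::solve_unitriangular(C, nn)),
                   unname(ni))
    }
  }
})
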