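test_that("printed closed forms: paw node orbit 14 and P4 end-edge orbit 4", {
  # paw a-b-c triangle, pendant d on a: nn14(b) = d(a) + d(c) - 4 = 1
  nn <- quad_noninduced(edges_paw(), level = "node")
  expect_equal(nn$o14[nn$node == "b"], 1)
  expect_equal(nn$o14[nn$node == "c"], 1)
  expect_equal(nn$o14[nn$node == "a"], 0)

  # K4: nn14(u) = sum over 3 triangle pairs of (3 + 3 - 4) = 6
  nn_k4 <- quad_noninduced(edges_k(4), level = "node")
  expect_equal(nn_k4$o14, rep(6, 4))

  # P4 a-b-c-d: en4 = 1 on an end edge, 0 on the middle edge
  en <- quad_noninduced(edges_path(4), level = "edge")
  expect_equal(en$o4, c(1, 0, 1))
})

test_that("frozen coefficient systems equal their derivation and honour the ei10 pins", {
  for (level in c("node", "edge")) {
    C <- quad_coefficients(level)
    expect_identical(C, derive_quad_coefficients(level))
    expect_true(all(diag(C) == 1))
    expect_true(all(C >= 0))
    expect_true(all(C == round(C)))
  }
  Ce <- quad_coefficients("edge")
  # ei10(e) = en10(e) - ei11(e) - 2 ei13(e)
  expect_equal(unname(Ce["o10", c("o11", "o12", "o13")]), c(1, 0, 2))
  Cn <- quad_coefficients("node")
  expect_equal(unname(Cn["o14", "o19"]), 6)
})

test_that("induced conversion reproduces the worked C4-in-denser-quads cases", {
  # diamond: cycle edges have en10 = 1 but ei10 = 0 (only quad is the diamond)
  qc <- quad_census(edges_diamond(), level = "edge")
  nn <- qc$counts$edge_noninduced
  ni <- qc$counts$edge_induced
  cycle_edges <- !(nn$u == "1" & nn$v == "2")
  expect_equal(nn$o10[cycle_edges], rep(1, 4))
  expect_equal(ni$o10, rep(0, 5))
  expect_equal(ni$o11[cycle_edges], rep(1, 4))
  expect_equal(ni$o12[!cycle_edges], 1)

  # K4 edge: en10 = 2, ei11 = 0, ei13 = 1 => ei10 = 0
  qk <- quad_census(edges_k(4), level = "edge")
  expect_equal(qk$counts$edge_noninduced$o10, rep(2, 6))
  expect_equal(qk$counts$edge_induced$o10, rep(0, 6))
  expect_equal(qk$counts$edge_induced$o13, rep(1, 6))

  # C4: the graph is its own induced C4
  qc4 <- quad_census(edges_cycle(4), level = "edge")
  expect_equal(qc4$counts$edge_induced$o10, rep(1, 4))
})

test_that("node and edge censuses match brute force on a random suite", {
  for (i in 1:30) {
    g <- rand_undirected(i, nmax = 22)
    ref <- brute_quad_census(g)
    sc <- quad_scan(g)
    nn <- orbcensus:::nn_node_matrix(g, sc$raw)
    en <- orbcensus:::nn_edge_matrix(g, sc$raw)
    expect_equal(unname(nn), unname(ref$node_noninduced))
    expect_equal(unname(en), unname(ref$edge_noninduced))
    expect_equal(unname(induced_from_noninduced(nn, "node")),
                 unname(ref$node_induced))
    expect_equal(unname(induced_from_noninduced(en, "edge")),
                 unname(ref$edge_induced))
  }
})

test_that("nn = C ni holds as an identity between independent computations", {
  Cn <- quad_coefficients("node")
  Ce <- quad_coefficients("edge")
  for (i in 31:45) {
    g <- rand_undirected(i, nmax = 18)
    ref <- brute_quad_census(g)          # induced counts by enumeration
    sc <- quad_scan(g)                   # non-induced by closed forms
    nn <- orbcensus:::nn_node_matrix(g, sc$raw)
    en <- orbcensus:::nn_edge_matrix(g, sc$raw)
    expect_equal(unname(nn), unname(ref$node_induced %*% t(Cn)))
    expect_equal(unname(en), unname(ref$edge_induced %*% t(Ce)))
  }
})

test_that("induced counts conserve totals per node, per edge and globally", {
  for (i in 46:60) {
    g <- rand_undirected(i, nmax = 25)
    qc <- quad_census(g, level = "node")
    ni <- orbit_matrix(qc$counts$node_induced)
    expect_equal(unname(rowSums(ni)), rep(choose(g$n - 1, 3), g$n))
    qe <- quad_census(g, level = "edge")
    ei <- orbit_matrix(qe$counts$edge_induced)
    expect_equal(unname(rowSums(ei)), rep(choose(g$n - 2, 2), g$m))
    census <- quad_census(g, level = "graph")$counts$graph$count
    expect_equal(sum(census), choose(g$n, 4))
  }
})

test_that("complement duality permutes the induced node census", {
  # quad <-> co-quad orbit permutation (0-based orbits)
  perm <- c(19, 17, 18, 16, 14, 13, 15, 12, 11, 10, 9, 8, 7, 5, 4, 6, 3, 1,
            2, 0)
  for (i in 61:70) {
    g <- rand_undirected(i, nmax = 20)
    h <- complement_graph(g)
    ni_g <- orbit_matrix(quad_census(g, level = "node")$counts$node_induced)
    ni_h <- orbit_matrix(quad_census(h, level = "node")$counts$node_induced)
    expect_equal(unname(ni_g), unname(ni_h[, perm + 1]))
  }
})

test_that("graphs with fewer than four nodes give zero counts, not errors", {
  tri <- quad_census(edges_cycle(3), level = "node")
  expect_true(all(orbit_matrix(tri$counts$node_induced) == 0))
  expect_equal(sum(quad_census(edges_cycle(3), level = "graph")$counts$graph$count), 0)
})

test_that("isolated nodes land entirely in disconnected orbits", {
  g <- undirected_graph(edges_k(4), nodes = 1:6)
  nn <- quad_noninduced(g, level = "node")
  iso <- nn[nn$node %in% c("5", "6"), ]
  expect_equal(iso$o0, rep(choose(5, 3), 2))
  # all orbits that put an edge at the anchor are empty
  with_edge <- paste0("o", c(1, 3, 4, 5, 7, 9, 10, 11, 12, 13, 14, 15, 16,
                             17, 18, 19))
  expect_true(all(as.matrix(iso[, with_edge]) == 0))
})

test_that("inconsistent non-induced input is rejected by the conversion", {
  g <- rand_undirected(3)
  nn <- orbit_matrix(quad_noninduced(g, level = "node"))
  nn[1, "o1"] <- nn[1, "o1"] + 1   # break an invariant
  expect_error(induced_from_noninduced(nn, "node"), "non-integer|negative")
  bad <- matrix(0, 4, 20)
  bad[1, 1] <- 1   # a lone empty-quad count cannot divide by four
  expect_error(graph_quad_census(bad), "not exact")
})

test_that("quad census tidiers and plot methods work", {
  qc <- quad_census(edges_k(4), level = "node")
  td <- tidy(qc)
  expect_true(all(c("orbit", "quad", "kind", "count") %in% names(td)))
  expect_equal(sum(td$count[td$kind == "induced" & td$orbit == 19]), 4)
  gl <- glance(qc)
  expect_equal(gl$degeneracy, 3L)
  expect_s3_class(autoplot(qc), "ggplot")
})
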