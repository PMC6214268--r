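test_that("dyad-pattern codes follow the weighted-sum encoding", {
  g <- directed_graph(rbind(c(1, 2)), nodes = 1:3)
  expect_equal(code_of_triple(g, 1, 2, 3), 1L)   # single arc (u,v)
  empty <- directed_graph(matrix(integer(0), 0, 2), nodes = 1:3)
  expect_equal(code_of_triple(empty, 1, 2, 3), 0L)
  full <- gen_gnp(3, 1, directed = TRUE, reciprocation = 1)
  expect_equal(code_of_triple(full, 1, 2, 3), 63L)
  expect_error(code_of_triple(g, 1, 1, 2), "distinct")
})

test_that("the code/orbit table has the required structure", {
  tab <- code_orbit_table()
  expect_equal(nrow(tab), 64)
  expect_setequal(unique(tab$triad), orbcensus:::triad_class_names())
  expect_equal(unlist(tab[tab$code == 0, c("orbit_u", "orbit_v", "orbit_w")],
                      use.names = FALSE), c(0, 0, 0))
  expect_equal(tab$triad[tab$code == 0], "003")
  expect_equal(unlist(tab[tab$code == 63, c("orbit_u", "orbit_v", "orbit_w")],
                      use.names = FALSE), c(35, 35, 35))
  expect_equal(tab$triad[tab$code == 63], "300")

  # orbits 21..35 are exactly the triads whose underlying graph is a triangle
  triangle_classes <- c("030T", "030C", "120D", "120U", "120C", "210", "300")
  omat <- as.matrix(tab[, c("orbit_u", "orbit_v", "orbit_w")])
  for (r in seq_len(64)) {
    in_triangle <- tab$triad[r] %in% triangle_classes
    expect_equal(all(omat[r, ] >= 21), in_triangle)
  }

  # every class uses exactly its canonical orbit block
  blocks <- orbcensus:::triad_blocks()
  for (lb in names(blocks)) {
    used <- sort(unique(as.vector(omat[tab$triad == lb, ])))
    expect_equal(used, sort(blocks[[lb]]), ignore_attr = TRUE)
  }

  # only 003, 030C and 300 have a single node orbit
  all_equal <- tab$triad[omat[, 1] == omat[, 2] & omat[, 2] == omat[, 3]]
  expect_setequal(unique(all_equal), c("003", "030C", "300"))
})

test_that("triad census worked examples", {
  cyc <- triad_census(data.frame(from = c("a", "b", "c"),
                                 to = c("b", "c", "a")))
  expect_equal(cyc$counts$node$o21, rep(1, 3))
  expect_equal(sum(orbit_matrix(cyc$counts$node)), 3)
  gr <- cyc$counts$graph
  expect_equal(gr$count[gr$triad == "030C"], 1)

  empty4 <- triad_census(directed_graph(matrix(integer(0), 0, 2), nodes = 1:4))
  expect_equal(empty4$counts$node$o0, rep(3, 4))

  # one mutual dyad {a,b} plus isolated c: block {4,5}
  md <- triad_census(directed_graph(rbind(c(1, 2), c(2, 1)), nodes = 1:3))
  expect_equal(md$counts$node$o5, c(1, 1, 0))
  expect_equal(md$counts$node$o4, c(0, 0, 1))

  full4 <- triad_census(gen_gnp(4, 1, directed = TRUE, reciprocation = 1))
  gr4 <- full4$counts$graph
  expect_equal(gr4$count[gr4$triad == "300"], 4)
})

test_that("node triad census equals brute force on a random suite", {
  for (i in 1:40) {
    g <- rand_directed(i)
    ref <- brute_triad_census(g)
    tc <- triad_census(g)
    expect_equal(unname(tc$node_matrix), unname(ref$node))
    expect_equal(graph_triad_census(tc), ref$graph)
  }
})

test_that("arc reversal swaps the D and U classes and fixes the rest", {
  swap <- c("021D" = "021U", "021U" = "021D", "111D" = "111U",
            "111U" = "111D", "120D" = "120U", "120U" = "120D")
  for (i in 41:55) {
    g <- rand_directed(i)
    a <- graph_triad_census(triad_census(g))
    b <- graph_triad_census(triad_census(reverse_graph(g)))
    for (lb in names(a)) {
      target <- if (lb %in% names(swap)) swap[[lb]] else lb
      expect_equal(unname(a[lb]), unname(b[target]))
    }
  }
})

test_that("triad conservation and underlying-triangle consistency", {
  for (i in 56:70) {
    g <- rand_directed(i)
    tc <- triad_census(g)
    mat <- tc$node_matrix
    expect_equal(unname(rowSums(mat)), rep(choose(g$n - 1, 2), g$n))
    expect_equal(sum(graph_triad_census(tc)), choose(g$n, 3))
    ug <- underlying_undirected(g)
    n_tri <- quad_scan(ug)$n_triangles
    expect_equal(sum(mat[, paste0("o", 21:35)]), 3 * n_tri)
  }
})

test_that("graph-level census agrees with an independent implementation", {
  skip_if_not_installed("igraph")
  ig_order <- c("003", "012", "102", "021D", "021U", "021C", "111D", "111U",
                "030T", "030C", "201", "120D", "120U", "120C", "210", "300")
  for (i in 71:75) {
    g <- rand_directed(i)
    ours <- graph_triad_census(triad_census(g))
    ig <- igraph::add_edges(igraph::make_empty_graph(n = g$n, directed = TRUE),
                            as.vector(t(g$arcs)))
    theirs <- igraph::triad_census(ig)
    expect_equal(unname(ours[ig_order]), as.numeric(theirs))
  }
})

test_that("triad tidiers and plot methods work", {
  tc <- triad_census(gen_gnp(8, 0.3, seed = 5, directed = TRUE))
  td <- tidy(tc)
  expect_true(all(c("node", "orbit", "triad", "count") %in% names(td)))
  expect_equal(sum(td$count), 8 * choose(7, 2))
  expect_s3_class(autoplot(tc), "ggplot")
  expect_equal(glance(tc)$n_triads, choose(8, 3))
})
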