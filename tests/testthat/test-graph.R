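test_that("edge lists are parsed, deduplicated and validated", {
  f <- withr::local_tempfile(lines = c("# comment", "a b", "b c", ""))
  g <- read_edge_list(f)
  expect_equal(g$n, 3)
  expect_equal(g$m, 2)
  expect_equal(sum(g$degree) / 2, g$m)

  f2 <- withr::local_tempfile(lines = c("a b", "b a"))
  g2 <- read_edge_list(f2)
  expect_equal(g2$m, 1)
  expect_equal(g2$n_dropped, 1L)

  d2 <- read_edge_list(f2, directed = TRUE)
  expect_equal(d2$m, 2)
  expect_equal(d2$d_mut, c(1, 1))

  f3 <- withr::local_tempfile(lines = c("a b", "oops", "b c"))
  expect_error(read_edge_list(f3), "line 2")
  f4 <- withr::local_tempfile(lines = c("a a"))
  expect_error(read_edge_list(f4), "self-loop")
})

test_that("node identifiers are preserved and isolated nodes supported", {
  g <- undirected_graph(data.frame(c("x", "y"), c("y", "z")),
                        nodes = c("x", "y", "z", "lonely"))
  expect_equal(g$n, 4)
  expect_equal(g$degree[match("lonely", g$nodes)], 0L)
  expect_error(undirected_graph(data.frame("x", "y"), nodes = "x"),
               "missing endpoint")
  et <- edge_tibble(g)
  expect_equal(et$from, c("x", "y"))
})

test_that("underlying undirected graph carries direction flags", {
  d <- directed_graph(rbind(c(1, 2), c(2, 1), c(2, 3)))
  u <- underlying_undirected(d)
  expect_equal(u$m, 2)
  mut_edge <- which(u$l_fwd & u$l_rev)
  expect_length(mut_edge, 1)
  one_way <- which(xor(u$l_fwd, u$l_rev))
  expect_length(one_way, 1)

  cyc <- directed_graph(rbind(c(1, 2), c(2, 3), c(3, 1)))
  ucyc <- underlying_undirected(cyc)
  expect_equal(ucyc$m, 3)
  expect_equal(quad_scan(ucyc)$n_triangles, 1)
  # flags reconstruct every original arc and nothing else
  n <- cyc$n
  arcs <- rbind(ucyc$edges[ucyc$l_fwd, , drop = FALSE],
                ucyc$edges[ucyc$l_rev, 2:1, drop = FALSE])
  expect_setequal((arcs[, 1] - 1) * n + arcs[, 2], cyc$arc_keys)
})

test_that("directed container tracks in/out/mutual degrees consistently", {
  for (i in 1:20) {
    g <- rand_directed(i)
    expect_equal(sum(g$d_out), g$m)
    expect_equal(sum(g$d_in), g$m)
    expect_equal(g$d_mut,
                 as.numeric(vapply(seq_len(g$n), function(v) {
                   length(intersect(g$out_adj[[v]], g$in_adj[[v]]))
                 }, numeric(1))))
  }
})
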