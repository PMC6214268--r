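test_that("smallest-last order removes minimum-degree nodes", {
  k5 <- undirected_graph(edges_k(5))
  o <- smallest_last_order(k5)
  expect_equal(attr(o, "degeneracy"), 4L)

  path <- undirected_graph(edges_path(4))
  op <- smallest_last_order(path)
  expect_equal(attr(op, "degeneracy"), 1L)
  # first removal is an endpoint of the path
  expect_true(op[1] %in% c(1L, 4L))

  star <- undirected_graph(edges_star(5), nodes = 1:6)
  os <- smallest_last_order(star)
  expect_equal(attr(os, "degeneracy"), 1L)
  expect_equal(unname(os[6]), 6L)  # centre removed after all leaves
})

test_that("smallest-last degeneracy matches a naive reference on 100 random graphs", {
  for (i in 1:100) {
    set.seed(i)
    n <- sample(5:50, 1)
    g <- gen_gnp(n, stats::runif(1, 0.02, 0.5), seed = 30000 + i)
    o <- smallest_last_order(g)
    expect_identical(attr(o, "degeneracy"), naive_degeneracy(g))
    og <- orient_acyclic(g, o)
    expect_equal(max(c(0L, og$d_out)), attr(o, "degeneracy"))
  }
})

test_that("acyclic orientation directs edges along the order", {
  tri <- undirected_graph(data.frame(c("a", "b", "c"), c("b", "c", "a")))
  og <- orient_acyclic(tri, order = 1:3)
  expect_equal(og$out_adj[[1]], c(2L, 3L))
  expect_equal(og$out_adj[[2]], 3L)
  expect_equal(max(og$d_out), 2L)

  k4 <- undirected_graph(edges_k(4))
  expect_equal(max(orient_acyclic(k4)$d_out), 3L)

  # any tree has degeneracy 1
  set.seed(1)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    parent <- vapply(2:n, function(v) sample(v - 1, 1), integer(1))
    tree <- undirected_graph(cbind(parent, 2:n))
    expect_equal(max(orient_acyclic(tree)$d_out), 1L)
  }
})

test_that("orientation invariants: acyclicity and degree conservation", {
  for (i in 1:20) {
    g <- rand_undirected(i)
    og <- orient_acyclic(g)
    expect_equal(sum(og$d_out), g$m)
    expect_equal(og$d_out + og$d_in, g$degree)
    # every arc goes from earlier to later in removal order
    for (v in seq_len(g$n)) {
      if (length(og$out_adj[[v]])) {
        expect_true(all(og$rank[og$out_adj[[v]]] > og$rank[v]))
      }
    }
  }
  expect_error(orient_acyclic(rand_undirected(1), order = c(1L, 1L)),
               "permutation")
})
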