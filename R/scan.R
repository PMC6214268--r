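#' Triangle / K4 / non-induced-C4 scan
#'
#' One pass over the degeneracy-oriented graph that (i) lists every triangle
#' and every K4 exactly once, (ii) counts non-induced four-cycles per node
#' and per edge by common-neighbour multiplicities anchored at the latest
#' cycle node, and (iii) accumulates the triangle-based degree and triangle
#' aggregates the closed-form non-induced orbit counts need. These are the
#' only subgraphs ever materialised; everything else in the quad census is
#' arithmetic on this output.
#'
#' @param x an `undirected_graph`, or an edge data frame / matrix.
#' @param triangles also return the triangle list (one row per triangle,
#'   internal node indices) — needed by the triad census.
#' @return a `quad_scan` object with tibbles `nodes` (degree, `t`, `k4`,
#'   `c4`) and `edges` (`t`, `k4`, `c4`), the removal `order`, `degeneracy`,
#'   `max_outdegree`, the triangle total, and `ops`, the inner-loop
#'   operation counters of the three stages (used to check the scan scales
#'   like its arboricity-based bounds rather than quadratically).
#' @examples
#' qs <- quad_scan(data.frame(u = c(1, 2, 3, 4), v = c(2, 3, 4, 1)))
#' qs$nodes
#' @export
quad_scan <- function(x, triangles = FALSE) {
  g <- as_graph(x)
  raw <- quad_scan_cpp(g$edges, g$n, isTRUE(triangles))
  structure(list(
    graph = g,
    nodes = tibble::tibble(
      node = g$nodes,
      degree = g$degree,
      t = raw$t_node,
      k4 = raw$k4_node,
      c4 = raw$c4_node
    ),
    edges = tibble::tibble(
      u = g$nodes[g$edges[, 1L]],
      v = g$nodes[g$edges[, 2L]],
      t = raw$t_edge,
      k4 = raw$k4_edge,
      c4 = raw$c4_edge
    ),
    order = raw$order,
    degeneracy = raw$degeneracy,
    max_outdegree = raw$max_outdegree,
    n_triangles = raw$n_triangles,
    ops = raw$ops,
    raw = raw
  ), class = "quad_scan")
}

#' @export
print.quad_scan <- function(x, ...) {
  cat("<quad_scan> n =", x$graph$n, ", m =", x$graph$m,
      ", degeneracy =", x$degeneracy, "\n")
  cat("  triangles:", x$n_triangles,
      " K4s:", sum(x$nodes$k4) / 4,
      " non-induced C4s:", sum(x$nodes$c4) / 4, "\n")
  invisible(x)
}
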