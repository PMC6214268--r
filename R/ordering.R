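#' Smallest-last (minimum-degree-removal) node ordering
#'
#' Repeatedly deletes a minimum-degree node of the remaining graph; ties are
#' broken by the smallest internal node index, so the output is
#' deterministic. The largest degree seen at removal time is the graph's
#' degeneracy, returned as an attribute.
#'
#' @param g an `undirected_graph`.
#' @return an integer vector of internal node indices in removal order, with
#'   the external identifiers as names and attribute `degeneracy`.
#' @examples
#' g <- undirected_graph(data.frame(c("a", "b", "c"), c("b", "c", "a")))
#' smallest_last_order(g)
#' @export
smallest_last_order <- function(g) {
  stopifnot(inherits(g, "undirected_graph"))
  res <- sl_order_cpp(g$edges, g$n)
  out <- res$order
  names(out) <- g$nodes[out]
  attr(out, "degeneracy") <- res$degeneracy
  out
}

#' Acyclic orientation along a removal order
#'
#' Directs every edge from its earlier endpoint (in removal order) to its
#' later endpoint. The orientation is acyclic by construction; with a
#' smallest-last order the maximum outdegree equals the graph's degeneracy.
#'
#' @param g an `undirected_graph`.
#' @param order a permutation of `1:g$n` (internal indices), e.g. from
#'   [smallest_last_order()].
#' @return an `oriented_graph`: the base graph plus `order`, `rank`,
#'   out-/in-adjacency lists and out-/in-degrees of the orientation.
#' @export
orient_acyclic <- function(g, order = smallest_last_order(g)) {
  stopifnot(inherits(g, "undirected_graph"))
  order <- as.integer(order)
  if (length(order) != g$n || anyNA(order) ||
      !setequal(order, seq_len(g$n))) {
    stop("`order` must be a permutation of the graph's node indices",
         call. = FALSE)
  }
  rank <- integer(g$n)
  rank[order] <- seq_len(g$n)
  em <- g$edges
  first_earlier <- rank[em[, 1L]] < rank[em[, 2L]]
  tail <- as.integer(ifelse(first_earlier, em[, 1L], em[, 2L]))
  head <- as.integer(ifelse(first_earlier, em[, 2L], em[, 1L]))
  structure(list(
    base = g,
    order = order,
    rank = rank,
    out_adj = split_adjacency(tail, head, g$n),
    in_adj = split_adjacency(head, tail, g$n),
    d_out = tabulate(tail, nbins = g$n),
    d_in = tabulate(head, nbins = g$n)
  ), class = "oriented_graph")
}

#' @export
print.oriented_graph <- function(x, ...) {
  cat("<oriented_graph> n =", x$base$n, ", m =", x$base$m,
      ", max outdegree =", max(c(0L, x$d_out)), "\n")
  invisible(x)
}
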