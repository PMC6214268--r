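# Closed-form non-induced orbit counts from the scan output. Primitive
# statistics: degrees d, neighbour aggregates (S = sum of neighbour degrees,
# Q = sum of squared neighbour degrees, S2 = sum of neighbour S, Tn = sum of
# neighbour triangle counts, H = sum over incident edges of C(t(e), 2)),
# per-node/per-edge triangle, K4 and non-induced C4 counts, and the
# triangle-pass aggregates A, B (node) and D, M (edge) from quad_scan().
nn_node_matrix <- function(g, raw) {
  n <- g$n
  m <- g$m
  out <- matrix(0, n, 20, dimnames = list(g$nodes, paste0("o", 0:19)))
  if (n < 4) return(out)
  E <- g$edges
  d <- as.numeric(g$degree)
  nbr_sum <- function(x) {
    acc_sum(c(E[, 1], E[, 2]), c(x[E[, 2]], x[E[, 1]]), n)
  }
  t_n <- raw$t_node
  S <- nbr_sum(d)
  Q <- nbr_sum(d^2)
  S2 <- nbr_sum(S)
  Tn <- nbr_sum(t_n)
  H <- acc_sum(c(E[, 1], E[, 2]), rep(choose2(raw$t_edge), 2), n)
  W <- sum(choose2(d))        # total paths of length two
  Tg <- sum(t_n) / 3          # total triangles

  out[, "o0"] <- choose(n - 1, 3)
  out[, "o1"] <- d * choose(n - 2, 2)
  out[, "o2"] <- (m - d) * (n - 3)
  out[, "o3"] <- d * (m - d + 1) - S
  out[, "o4"] <- (S - d) * (n - 3)
  out[, "o5"] <- choose2(d) * (n - 3)
  out[, "o6"] <- W - choose2(d) - (S - d)
  out[, "o7"] <- t_n * (n - 3)
  out[, "o8"] <- Tg - t_n
  out[, "o9"] <- S2 - S - d^2 + d - 2 * t_n
  out[, "o10"] <- (d - 1) * (S - d) - 2 * t_n
  out[, "o11"] <- choose(d, 3)
  out[, "o12"] <- (Q - 3 * S + 2 * d) / 2
  out[, "o13"] <- Tn - 2 * t_n
  out[, "o14"] <- raw$A_node - 4 * t_n
  out[, "o15"] <- t_n * (d - 2)
  out[, "o16"] <- raw$c4_node
  out[, "o17"] <- raw$B_node - t_n
  out[, "o18"] <- H
  out[, "o19"] <- raw$k4_node
  out
}

nn_edge_matrix <- function(g, raw) {
  n <- g$n
  m <- g$m
  out <- matrix(0, m, 14, dimnames = list(NULL, paste0("o", 0:13)))
  if (n < 4 || m == 0) return(out)
  E <- g$edges
  d <- as.numeric(g$degree)
  S <- acc_sum(c(E[, 1], E[, 2]), c(d[E[, 2]], d[E[, 1]]), n)
  du <- d[E[, 1]]
  dv <- d[E[, 2]]
  tu <- raw$t_node[E[, 1]]
  tv <- raw$t_node[E[, 2]]
  te <- raw$t_edge

  out[, "o0"] <- choose(n - 2, 2)
  out[, "o1"] <- m - du - dv + 1
  out[, "o2"] <- (du + dv - 2) * (n - 3)
  out[, "o3"] <- te * (n - 3)
  out[, "o4"] <- S[E[, 1]] + S[E[, 2]] - 2 * (du + dv) + 2 - 2 * te
  out[, "o5"] <- (du - 1) * (dv - 1) - te
  out[, "o6"] <- choose2(du - 1) + choose2(dv - 1)
  out[, "o7"] <- tu + tv - 2 * te
  out[, "o8"] <- te * (du + dv - 4)
  out[, "o9"] <- raw$D_edge - 2 * te
  out[, "o10"] <- raw$c4_edge
  out[, "o11"] <- raw$M_edge - 2 * te
  out[, "o12"] <- choose2(te)
  out[, "o13"] <- raw$k4_edge
  out
}

#' Non-induced quad orbit counts
#'
#' All 20 per-node (or 14 per-edge) non-induced orbit counts, each from a
#' closed-form combination of the scan statistics — no 4-subset is ever
#' enumerated. Two of the formulas are classical anchors: the paw count with
#' the anchor as the degree-2 triangle node,
#' \eqn{nn_{14}(u) = \sum_{\{v,w\} \in T(u)} (d(v)+d(w)-4)}, and the P4
#' end-edge count
#' \eqn{en_4(u,v) = S(u) + S(v) - 2(d(u)+d(v)) + 2 - 2t(u,v)}.
#'
#' @param x an `undirected_graph` or edge table.
#' @param level `"node"` or `"edge"`.
#' @param scan optionally a precomputed [quad_scan()] of the same graph.
#' @return a tibble: `node` plus `o0..o19`, or `u`, `v` plus `o0..o13`.
#' @export
quad_noninduced <- function(x, level = c("node", "edge"), scan = NULL) {
  level <- match.arg(level)
  g <- as_graph(x)
  if (is.null(scan)) scan <- quad_scan(g)
  if (level == "node") {
    mat <- nn_node_matrix(g, scan$raw)
    tibble::as_tibble(cbind(tibble::tibble(node = g$nodes),
                            tibble::as_tibble(mat)))
  } else {
    mat <- nn_edge_matrix(g, scan$raw)
    tibble::as_tibble(cbind(
      tibble::tibble(u = g$nodes[g$edges[, 1L]], v = g$nodes[g$edges[, 2L]]),
      tibble::as_tibble(mat)))
  }
}

#' Convert non-induced to induced orbit counts
#'
#' Solves `noninduced = C %*% induced` exactly by back-substitution in
#' density order, where `C` is the frozen unitriangular coefficient system
#' for the level. Any negative or non-integer component signals an
#' inconsistent input and raises an error.
#'
#' @param counts tibble (as returned by [quad_noninduced()]) or bare count
#'   matrix of non-induced counts.
#' @param level `"node"` or `"edge"`; inferred from the column count when
#'   missing.
#' @return induced counts in the same shape as the input.
#' @export
induced_from_noninduced <- function(counts, level = NULL) {
  is_tbl <- is.data.frame(counts)
  ocols <- grep("^o[0-9]+$", if (is_tbl) names(counts) else colnames(counts))
  mat <- if (is_tbl) as.matrix(counts[, ocols]) else counts[, ocols, drop = FALSE]
  if (is.null(level)) level <- if (ncol(mat) == 20) "node" else "edge"
  C <- quad_coefficients(level)
  k <- ncol(C)
  if (ncol(mat) != k) stop("count table has the wrong number of orbits",
                           call. = FALSE)
  ni <- solve_unitriangular(C, mat)
  if (any(ni < 0) || any(ni != round(ni))) {
    stop("induced counts are negative or non-integer: ",
         "inconsistent non-induced input", call. = FALSE)
  }
  if (is_tbl) {
    counts[, ocols] <- tibble::as_tibble(ni)
    counts
  } else {
    dimnames(ni) <- dimnames(mat)
    ni
  }
}

# back-substitution for x with nn = x %*% t(C) row-wise, i.e. per row of the
# count matrix: nn[o] = sum_{o' >= o} C[o, o'] x[o']; C unitriangular
solve_unitriangular <- function(C, nn) {
  k <- ncol(C)
  ni <- matrix(0, nrow(nn), k, dimnames = dimnames(nn))
  for (o in k:1) {
    rest <- if (o < k) {
      ni[, (o + 1):k, drop = FALSE] %*% C[o, (o + 1):k]
    } else 0
    ni[, o] <- nn[, o] - rest
  }
  ni
}

#' Frozen coefficient systems relating non-induced and induced counts
#'
#' The checked-in constant tables; [derive_quad_coefficients()] regenerates
#' them from the atlas and the package tests assert both agree.
#'
#' @param level `"node"` or `"edge"`.
#' @return integer matrix (20 x 20 or 14 x 14).
#' @export
quad_coefficients <- function(level = c("node", "edge")) {
  level <- match.arg(level)
  if (level == "node") quad_coef_node_frozen() else quad_coef_edge_frozen()
}

#' Orbit-aware quad census of an undirected graph
#'
#' The main entry point: runs the scan, evaluates the closed-form
#' non-induced orbit counts and converts them exactly to induced counts.
#'
#' @param x an `undirected_graph`, or an edge data frame / matrix (first two
#'   columns are endpoints).
#' @param level `"node"`, `"edge"` or `"graph"`.
#' @param kind `"both"` (default), `"induced"` or `"non_induced"`; the
#'   graph-level census is always induced.
#' @param nodes optional node identifiers to force into the graph (isolated
#'   nodes count in the disconnected orbits).
#' @return a `quad_census` object; its `counts` element holds the requested
#'   tibbles (`node_induced`, `node_noninduced`, `edge_*`, `graph`). Use
#'   [tidy()] for a long tibble, [glance()] for summary statistics and
#'   [autoplot()] for a quick orbit-distribution plot.
#' @examples
#' k4 <- data.frame(u = c(1, 1, 1, 2, 2, 3), v = c(2, 3, 4, 3, 4, 4))
#' qc <- quad_census(k4, level = "node")
#' qc$counts$node_induced
#' @export
quad_census <- function(x, level = c("node", "edge", "graph"),
                        kind = c("both", "induced", "non_induced"),
                        nodes = NULL) {
  level <- match.arg(level)
  kind <- match.arg(kind)
  g <- as_graph(x, nodes = nodes)
  sc <- quad_scan(g)
  counts <- list()
  need_node <- level %in% c("node", "graph")
  need_edge <- level == "edge"
  need_induced <- kind != "non_induced" || level == "graph"
  if (need_node) {
    nn <- nn_node_matrix(g, sc$raw)
    if (kind != "induced" && level == "node") {
      counts$node_noninduced <- orbit_tibble(g, nn, "node")
    }
    if (need_induced) {
      ni <- induced_from_noninduced(nn, "node")
      if (level == "node" && kind != "non_induced") {
        counts$node_induced <- orbit_tibble(g, ni, "node")
      }
      if (level == "graph") {
        counts$graph <- tibble::tibble(
          quad = quad_class_names(),
          count = graph_quad_census(ni)
        )
      }
    }
  }
  if (need_edge) {
    en <- nn_edge_matrix(g, sc$raw)
    if (kind != "induced") {
      counts$edge_noninduced <- orbit_tibble(g, en, "edge")
    }
    if (kind != "non_induced") {
      ei <- induced_from_noninduced(en, "edge")
      counts$edge_induced <- orbit_tibble(g, ei, "edge")
    }
  }
  structure(list(
    level = level, kind = kind, counts = counts, graph = g,
    degeneracy = sc$degeneracy, n_triangles = sc$n_triangles,
    n_k4 = sum(sc$raw$k4_node) / 4, n_c4_noninduced = sum(sc$raw$c4_node) / 4,
    ops = sc$ops
  ), class = "quad_census")
}

orbit_tibble <- function(g, mat, level) {
  if (level == "node") {
    tibble::as_tibble(cbind(tibble::tibble(node = g$nodes),
                            tibble::as_tibble(unname_rows(mat, NULL))))
  } else {
    tibble::as_tibble(cbind(
      tibble::tibble(u = g$nodes[g$edges[, 1L]], v = g$nodes[g$edges[, 2L]]),
      tibble::as_tibble(unname_rows(mat, NULL))))
  }
}

#' Graph-level quad census from induced node counts
#'
#' Every quad contains four nodes, so the census of quad `Q` is the sum of
#' its orbit counts over all nodes divided by four; the division must be
#' exact, anything else signals inconsistent counts.
#'
#' @param ni_node induced per-node counts: the matrix/tibble from
#'   [quad_census()]/[quad_noninduced()] pipelines (columns `o0..o19`).
#' @return named numeric vector of length 11 in density order.
#' @export
graph_quad_census <- function(ni_node) {
  if (is.data.frame(ni_node)) {
    ni_node <- as.matrix(ni_node[, grep("^o[0-9]+$", names(ni_node))])
  }
  tot <- colSums(ni_node)
  counts <- acc_sum(node_orbit_class(), tot, 11) / 4
  if (any(counts != round(counts))) {
    stop("graph census division is not exact: inconsistent orbit counts",
         call. = FALSE)
  }
  stats::setNames(counts, quad_class_names())
}

#' @export
print.quad_census <- function(x, ...) {
  cat("<quad_census> level =", x$level, ", kind =", x$kind,
      "| n =", x$graph$n, ", m =", x$graph$m, "\n")
  for (nm in names(x$counts)) {
    cat("  $counts$", nm, ": ", nrow(x$counts[[nm]]), " rows\n", sep = "")
  }
  invisible(x)
}
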