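#' Simple graph containers
#'
#' `undirected_graph()` and `directed_graph()` build validated simple-graph
#' objects from an edge (or arc) table. External node identifiers may be any
#' atomic values; internally nodes are dense 1-based integers and the mapping
#' is kept in `$nodes`. Self-loops are rejected; duplicate edges (including
#' an undirected edge listed in both directions) are silently deduplicated
#' and the number dropped is recorded in `$n_dropped`.
#'
#' @param edges a data frame or two-column matrix; the first two columns are
#'   the endpoints of each edge (tail and head for directed graphs).
#' @param nodes optional vector of node identifiers to include even when they
#'   have no incident edge (isolated nodes still have nonzero counts in the
#'   disconnected orbits); must be a superset of the endpoint identifiers.
#' @return an object of class `undirected_graph` or `directed_graph` with
#'   fields `nodes`, `n`, `m`, the dense integer edge/arc matrix, degrees and
#'   adjacency lists.
#' @examples
#' g <- undirected_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
#' g$n
#' g$m
#' @export
undirected_graph <- function(edges, nodes = NULL) {
  ep <- as_endpoints(edges)
  ids <- make_node_ids(ep, nodes)
  u <- match(ep[[1L]], ids)
  v <- match(ep[[2L]], ids)
  if (any(u == v)) {
    stop("self-loops are not allowed (first at input row ",
         which(u == v)[1L], ")", call. = FALSE)
  }
  a <- pmin(u, v)
  b <- pmax(u, v)
  key <- (a - 1) * length(ids) + b
  keep <- !duplicated(key)
  n_dropped <- sum(!keep)
  em <- cbind(a[keep], b[keep])
  storage.mode(em) <- "integer"
  g <- structure(list(
    nodes = ids,
    n = length(ids),
    m = nrow(em),
    edges = em,
    degree = tabulate(em, nbins = length(ids)),
    adj = adjacency_from_edges(em, length(ids)),
    n_dropped = n_dropped
  ), class = "undirected_graph")
  g
}

#' @rdname undirected_graph
#' @export
directed_graph <- function(edges, nodes = NULL) {
  ep <- as_endpoints(edges)
  ids <- make_node_ids(ep, nodes)
  u <- match(ep[[1L]], ids)
  v <- match(ep[[2L]], ids)
  if (any(u == v)) {
    stop("self-loops are not allowed (first at input row ",
         which(u == v)[1L], ")", call. = FALSE)
  }
  key <- (u - 1) * length(ids) + v
  keep <- !duplicated(key)
  n_dropped <- sum(!keep)
  am <- cbind(u[keep], v[keep])
  storage.mode(am) <- "integer"
  n <- length(ids)
  akey <- sort((am[, 1L] - 1) * as.double(n) + am[, 2L])
  rkey <- (am[, 2L] - 1) * as.double(n) + am[, 1L]
  mutual <- keyed_lookup(akey, rkey)
  g <- structure(list(
    nodes = ids,
    n = n,
    m = nrow(am),
    arcs = am,
    arc_keys = akey,
    mutual_arc = mutual,  # per arc: is the reciprocal arc present?
    d_out = tabulate(am[, 1L], nbins = n),
    d_in = tabulate(am[, 2L], nbins = n),
    d_mut = acc_sum(am[, 1L][mutual], rep(1, sum(mutual)), n),
    out_adj = split_adjacency(am[, 1L], am[, 2L], n),
    in_adj = split_adjacency(am[, 2L], am[, 1L], n),
    n_dropped = n_dropped
  ), class = "directed_graph")
  g
}

as_endpoints <- function(edges) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    stop("`edges` must be a data frame or matrix with at least two columns",
         call. = FALSE)
  }
  list(as.character(edges[[1L]]), as.character(edges[[2L]]))
}

make_node_ids <- function(ep, nodes) {
  seen <- unique(c(ep[[1L]], ep[[2L]]))
  if (is.null(nodes)) return(seen)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("`nodes` contains duplicates", call. = FALSE)
  missing <- setdiff(seen, nodes)
  if (length(missing)) {
    stop("`nodes` is missing endpoint identifiers: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  nodes
}

adjacency_from_edges <- function(em, n) {
  split_adjacency(c(em[, 1L], em[, 2L]), c(em[, 2L], em[, 1L]), n)
}

split_adjacency <- function(from, to, n) {
  adj <- split(as.integer(to), factor(from, levels = seq_len(n)))
  names(adj) <- NULL
  adj
}

# for each value in `needles`, is it present in the sorted vector `haystack`?
keyed_lookup <- function(haystack, needles) {
  if (length(haystack) == 0L) return(rep(FALSE, length(needles)))
  pos <- findInterval(needles, haystack)
  pos > 0 & haystack[pmax(pos, 1L)] == needles
}

#' Read a whitespace-separated edge list
#'
#' One edge per line, two identifier tokens per line; `#` starts a comment
#' and blank lines are skipped. This is the only input format the package
#' requires.
#'
#' @param path file path or connection.
#' @param directed interpret lines as arcs (tail head) instead of edges.
#' @param nodes optional vector of node identifiers (see
#'   [undirected_graph()]); useful to keep isolated nodes present.
#' @return an `undirected_graph` or `directed_graph`.
#' @export
read_edge_list <- function(path, directed = FALSE, nodes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- lengths(toks) != 2L
  if (any(bad)) {
    stop("malformed edge list line ", which(keep)[bad][1L],
         ": expected two tokens", call. = FALSE)
  }
  if (!length(toks)) {
    ep <- data.frame(from = character(), to = character())
  } else {
    tm <- do.call(rbind, toks)
    ep <- data.frame(from = tm[, 1L], to = tm[, 2L],
                     stringsAsFactors = FALSE)
  }
  if (directed) directed_graph(ep, nodes = nodes)
  else undirected_graph(ep, nodes = nodes)
}

#' Write a graph as a plain-text edge list
#'
#' @param g an `undirected_graph` or `directed_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  em <- if (inherits(g, "directed_graph")) g$arcs else g$edges
  df <- data.frame(g$nodes[em[, 1L]], g$nodes[em[, 2L]])
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Underlying undirected graph of a digraph
#'
#' Collapses each adjacent ordered pair to a single undirected edge and
#' attaches per-edge direction flags: for the canonical edge `(a, b)` (with
#' `a < b` internally), `l_fwd` records whether the arc `a -> b` exists and
#' `l_rev` whether `b -> a` does. The flags give constant-time access to
#' `l(i, j)` when classifying triads.
#'
#' @param g a `directed_graph`.
#' @return an `undirected_graph` with extra fields `l_fwd` and `l_rev`.
#' @export
underlying_undirected <- function(g) {
  stopifnot(inherits(g, "directed_graph"))
  am <- g$arcs
  a <- pmin(am[, 1L], am[, 2L])
  b <- pmax(am[, 1L], am[, 2L])
  key <- (a - 1) * as.double(g$n) + b
  keep <- !duplicated(key)
  em <- cbind(a[keep], b[keep])
  storage.mode(em) <- "integer"
  fwd_keys <- sort((am[, 1L] - 1) * as.double(g$n) + am[, 2L])
  ekey <- (em[, 1L] - 1) * as.double(g$n) + em[, 2L]
  rkey <- (em[, 2L] - 1) * as.double(g$n) + em[, 1L]
  ug <- structure(list(
    nodes = g$nodes,
    n = g$n,
    m = nrow(em),
    edges = em,
    degree = tabulate(em, nbins = g$n),
    adj = adjacency_from_edges(em, g$n),
    n_dropped = 0L,
    l_fwd = keyed_lookup(fwd_keys, ekey),
    l_rev = keyed_lookup(fwd_keys, rkey)
  ), class = "undirected_graph")
  ug
}

# coerce user input (graph object, data frame, matrix) to a graph
as_graph <- function(x, directed = FALSE, nodes = NULL) {
  if (inherits(x, if (directed) "directed_graph" else "undirected_graph")) {
    return(x)
  }
  if (inherits(x, c("undirected_graph", "directed_graph"))) {
    stop("graph directedness does not match the requested census",
         call. = FALSE)
  }
  if (directed) directed_graph(x, nodes = nodes)
  else undirected_graph(x, nodes = nodes)
}

#' @export
print.undirected_graph <- function(x, ...) {
  cat("<undirected_graph> n =", x$n, ", m =", x$m, "edges\n")
  invisible(x)
}

#' @export
print.directed_graph <- function(x, ...) {
  cat("<directed_graph> n =", x$n, ", m =", x$m, "arcs (",
      sum(x$mutual_arc) / 2, "mutual dyads )\n")
  invisible(x)
}

#' Edge table of a graph as a tibble
#'
#' @param g a graph object.
#' @return a tibble with columns `from`, `to` in external identifiers.
#' @export
edge_tibble <- function(g) {
  em <- if (inherits(g, "directed_graph")) g$arcs else g$edges
  tibble::tibble(from = g$nodes[em[, 1L]], to = g$nodes[em[, 2L]])
}
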