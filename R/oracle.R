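#' @name quad-orbits
#' @title Canonical quad and orbit enumeration
#'
#' @description
#' The eleven quads in density order: empty (4K1), co-diamond (K2 + 2K1),
#' co-C4 (2K2), co-paw (P3 + K1), co-claw (K3 + K1), P4, claw (K1,3), paw,
#' C4, diamond, K4. Node orbits 0..19 and edge orbits 0..13 follow this
#' order; within a quad, roles are distinguished by degree (e.g. claw centre
#' = node orbit 11, claw leaf = 12; diamond cycle edge = 11, diagonal = 12).
#' `quad_orbit_info()` tabulates the mapping.
NULL

quad_class_names <- function() {
  c("empty", "co-diamond", "co-C4", "co-paw", "co-claw", "P4",
    "claw", "paw", "C4", "diamond", "K4")
}

# class id (1..11) of each node orbit 0..19 / edge orbit 0..13
node_orbit_class <- function() {
  c(1L, 2L, 2L, 3L, 4L, 4L, 4L, 5L, 5L, 6L, 6L, 7L, 7L, 8L, 8L, 8L,
    9L, 10L, 10L, 11L)
}
edge_orbit_class <- function() {
  c(2L, 3L, 4L, 5L, 6L, 6L, 7L, 8L, 8L, 8L, 9L, 10L, 10L, 11L)
}

# number of edges of each quad class
quad_class_edges <- function() c(0L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L, 6L)

#' Orbit atlas for quads
#'
#' @return a list of two tibbles, `nodes` (orbit, quad, role degree) and
#'   `edges` (orbit, quad, endpoint degrees), describing the canonical
#'   numbering used throughout the package.
#' @export
quad_orbit_info <- function() {
  qn <- quad_class_names()
  nodes <- tibble::tibble(
    orbit = 0:19,
    quad = qn[node_orbit_class()],
    degree = c(0L, 1L, 0L, 1L, 1L, 2L, 0L, 2L, 0L, 1L, 2L, 3L, 1L, 1L,
               2L, 3L, 2L, 2L, 3L, 3L)
  )
  edges <- tibble::tibble(
    orbit = 0:13,
    quad = qn[edge_orbit_class()],
    endpoint_degrees = c("1-1", "1-1", "1-2", "2-2", "1-2", "2-2", "1-3",
                         "1-3", "2-3", "2-2", "2-2", "2-3", "3-3", "3-3")
  )
  list(nodes = nodes, edges = edges)
}

# the 6 unordered node pairs of a labelled 4-node graph, in bit order
quad_pairs <- function() {
  rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
}

# Atlas over all 2^6 labelled 4-node graphs: class of every edge mask, node
# orbit of every position, edge orbit of every present pair, and the
# sum-over-edge-subsets contribution tables that make both the brute-force
# oracle and the coefficient derivation pure table lookups.
quad_tables <- function() {
  cache_get("quad_tables", build_quad_tables)
}

build_quad_tables <- function() {
  pp <- quad_pairs()
  class_by_key <- c(
    "0:0000" = 1L, "1:0011" = 2L, "2:1111" = 3L, "2:0112" = 4L,
    "3:0222" = 5L, "3:1122" = 6L, "3:1113" = 7L, "4:1223" = 8L,
    "4:2222" = 9L, "5:2233" = 10L, "6:3333" = 11L)
  node_orbit_by_class_deg <- list(
    `1` = c(`0` = 0L),
    `2` = c(`0` = 2L, `1` = 1L),
    `3` = c(`1` = 3L),
    `4` = c(`0` = 6L, `1` = 4L, `2` = 5L),
    `5` = c(`0` = 8L, `2` = 7L),
    `6` = c(`1` = 9L, `2` = 10L),
    `7` = c(`1` = 12L, `3` = 11L),
    `8` = c(`1` = 13L, `2` = 14L, `3` = 15L),
    `9` = c(`2` = 16L),
    `10` = c(`2` = 17L, `3` = 18L),
    `11` = c(`3` = 19L))
  edge_orbit_by_class_degs <- list(
    `2` = c(`11` = 0L),
    `3` = c(`11` = 1L),
    `4` = c(`12` = 2L),
    `5` = c(`22` = 3L),
    `6` = c(`12` = 4L, `22` = 5L),
    `7` = c(`13` = 6L),
    `8` = c(`13` = 7L, `23` = 8L, `22` = 9L),
    `9` = c(`22` = 10L),
    `10` = c(`23` = 11L, `33` = 12L),
    `11` = c(`33` = 13L))

  cls <- integer(64)
  norb <- matrix(NA_integer_, 64, 4)
  eorb <- matrix(NA_integer_, 64, 6)
  bits <- matrix(0L, 64, 6)
  for (mask in 0:63) {
    b <- as.integer(bitwAnd(mask, 2^(0:5)) > 0)
    bits[mask + 1, ] <- b
    deg <- integer(4)
    for (k in 1:6) {
      if (b[k]) {
        deg[pp[k, 1]] <- deg[pp[k, 1]] + 1L
        deg[pp[k, 2]] <- deg[pp[k, 2]] + 1L
      }
    }
    key <- paste0(sum(b), ":", paste(sort(deg), collapse = ""))
    cl <- class_by_key[[key]]
    cls[mask + 1] <- cl
    norb[mask + 1, ] <- node_orbit_by_class_deg[[as.character(cl)]][as.character(deg)]
    for (k in 1:6) {
      if (b[k]) {
        dk <- sort(deg[pp[k, ]])
        eorb[mask + 1, k] <-
          edge_orbit_by_class_degs[[as.character(cl)]][paste(dk, collapse = "")]
      }
    }
  }

  submasks <- lapply(0:63, function(mask) {
    s <- 0:63
    s[bitwAnd(s, mask) == s]
  })

  # nn_node[(mask, position), orbit]: over all edge subsets of `mask`, how
  # often position p lands in each node orbit
  nn_node <- matrix(0, 64 * 4, 20)
  nn_edge <- matrix(0, 64 * 6, 14)
  for (mask in 0:63) {
    for (s in submasks[[mask + 1]]) {
      for (p in 1:4) {
        o <- norb[s + 1, p]
        nn_node[mask * 4 + p, o + 1] <- nn_node[mask * 4 + p, o + 1] + 1
      }
      for (k in 1:6) {
        if (bits[s + 1, k] == 1L) {
          o <- eorb[s + 1, k]
          nn_edge[mask * 6 + k, o + 1] <- nn_edge[mask * 6 + k, o + 1] + 1
        }
      }
    }
  }
  rep_mask <- vapply(1:11, function(cl) which(cls == cl)[1] - 1L, integer(1))
  list(class = cls, node_orbit = norb, edge_orbit = eorb, bits = bits,
       submasks = submasks, nn_node = nn_node, nn_edge = nn_edge,
       rep_mask = rep_mask)
}

#' Derive the non-induced/induced coefficient systems
#'
#' Entry `(o, o')` counts the edge-deletion embeddings of the sparser quad
#' into the denser quad that keep the anchored node (or edge) in orbit `o`
#' while the anchor sits in induced orbit `o'` — i.e. the number of spanning
#' edge subsets of the denser quad isomorphic to the sparser quad with the
#' anchor's role preserved. The matrices are unitriangular under the density
#' ordering of the orbits, so `noninduced = C %*% induced` can be inverted
#' exactly by back-substitution.
#'
#' @param level `"node"` (20 x 20) or `"edge"` (14 x 14).
#' @return an integer matrix with `dimnames` `o0..`; unit diagonal,
#'   upper-triangular in the canonical orbit order.
#' @export
derive_quad_coefficients <- function(level = c("node", "edge")) {
  level <- match.arg(level)
  tbl <- quad_tables()
  if (level == "node") {
    k <- 20L
    ocls <- node_orbit_class()
    find_anchor <- function(mask, o) which(tbl$node_orbit[mask + 1, ] == o)[1]
    contrib <- function(mask, p) tbl$nn_node[mask * 4 + p, ]
  } else {
    k <- 14L
    ocls <- edge_orbit_class()
    find_anchor <- function(mask, o) which(tbl$edge_orbit[mask + 1, ] == o)[1]
    contrib <- function(mask, p) tbl$nn_edge[mask * 6 + p, ]
  }
  C <- matrix(0, k, k)
  for (oo in seq_len(k)) {
    mask <- tbl$rep_mask[ocls[oo]]
    p <- find_anchor(mask, oo - 1L)
    C[, oo] <- contrib(mask, p)
  }
  dimnames(C) <- list(paste0("o", seq_len(k) - 1), paste0("o", seq_len(k) - 1))
  me <- quad_class_edges()
  for (o in seq_len(k)) {
    for (oo in seq_len(k)) {
      dense_ok <- o == oo || me[ocls[o]] < me[ocls[oo]]
      if (C[o, oo] != 0 && !dense_ok) {
        stop("coefficient derivation failed triangularity at (o",
             o - 1, ", o", oo - 1, ")", call. = FALSE)
      }
    }
  }
  if (any(diag(C) != 1)) {
    stop("coefficient derivation failed: non-unit diagonal", call. = FALSE)
  }
  C
}

#' Brute-force quad census (reference oracle)
#'
#' Classifies every 4-subset of nodes by an exhaustive atlas lookup and, for
#' non-induced counts, every edge subset of every induced quad. Exponential
#' in nothing but bounded by \eqn{\binom{n}{4} \cdot 2^6}; refuses graphs
#' with more than 40 nodes.
#'
#' @param x an `undirected_graph` or edge table.
#' @return list with matrices `node_induced`, `node_noninduced` (n x 20),
#'   `edge_induced`, `edge_noninduced` (m x 14) and the 11-long
#'   `graph` census.
#' @export
brute_quad_census <- function(x) {
  g <- as_graph(x)
  n <- g$n
  m <- g$m
  if (n > 40) stop("brute_quad_census: n > 40 is too large", call. = FALSE)
  node_i <- matrix(0, n, 20)
  node_n <- matrix(0, n, 20)
  edge_i <- matrix(0, m, 14)
  edge_n <- matrix(0, m, 14)
  graph_census <- stats::setNames(numeric(11), quad_class_names())
  colnames(node_i) <- colnames(node_n) <- paste0("o", 0:19)
  colnames(edge_i) <- colnames(edge_n) <- paste0("o", 0:13)
  out <- list(node_induced = node_i, node_noninduced = node_n,
              edge_induced = edge_i, edge_noninduced = edge_n,
              graph = graph_census)
  if (n < 4) return(out)

  tbl <- quad_tables()
  A <- matrix(FALSE, n, n)
  A[g$edges] <- TRUE
  A[g$edges[, 2:1, drop = FALSE]] <- TRUE
  eidm <- matrix(0L, n, n)
  eidm[g$edges] <- seq_len(m)
  eidm[g$edges[, 2:1, drop = FALSE]] <- seq_len(m)

  ss <- utils::combn(n, 4)
  pp <- quad_pairs()
  mask <- numeric(ncol(ss))
  bitlist <- vector("list", 6)
  for (k in 1:6) {
    bitlist[[k]] <- A[cbind(ss[pp[k, 1], ], ss[pp[k, 2], ])]
    mask <- mask + 2^(k - 1) * bitlist[[k]]
  }

  # node level (subset-major: the four positions of subset 1, then 2, ...)
  nodevec <- as.vector(ss)
  posvec <- rep(1:4, times = ncol(ss))
  maskvec <- rep(mask, each = 4)
  orb <- tbl$node_orbit[cbind(maskvec + 1, posvec)]
  node_i <- unclass(table(factor(nodevec, seq_len(n)), factor(orb, 0:19)))
  key <- maskvec * 4 + posvec           # 1-based row of tbl$nn_node
  cmat <- unclass(table(factor(nodevec, seq_len(n)), factor(key, 1:256)))
  node_n <- cmat %*% tbl$nn_node

  # edge level
  ev <- integer(0); eb <- integer(0); emask <- numeric(0)
  for (k in 1:6) {
    rows <- which(bitlist[[k]])
    if (!length(rows)) next
    ev <- c(ev, eidm[cbind(ss[pp[k, 1], rows], ss[pp[k, 2], rows])])
    eb <- c(eb, rep(k, length(rows)))
    emask <- c(emask, mask[rows])
  }
  if (length(ev)) {
    orb_e <- tbl$edge_orbit[cbind(emask + 1, eb)]
    edge_i <- unclass(table(factor(ev, seq_len(m)), factor(orb_e, 0:13)))
    ekey <- emask * 6 + eb
    cemat <- unclass(table(factor(ev, seq_len(m)), factor(ekey, 1:384)))
    edge_n <- cemat %*% tbl$nn_edge
  }

  graph_census[] <- tabulate(tbl$class[mask + 1], nbins = 11)
  storage.mode(node_i) <- "double"
  storage.mode(edge_i) <- "double"
  dimnames(node_i) <- dimnames(node_n) <-
    list(g$nodes, paste0("o", 0:19))
  dimnames(edge_i) <- dimnames(edge_n) <- list(NULL, paste0("o", 0:13))
  list(node_induced = node_i, node_noninduced = unname_rows(node_n, g$nodes),
       edge_induced = edge_i, edge_noninduced = unname_rows(edge_n, NULL),
       graph = graph_census)
}

unname_rows <- function(mat, rn) {
  dimnames(mat) <- list(rn, colnames(mat))
  mat
}

#' Brute-force triad census (reference oracle)
#'
#' Classifies every 3-subset of a digraph through the dyad-pattern code and
#' the frozen code/orbit table. Refuses graphs with more than 60 nodes.
#'
#' @param x a `directed_graph` or arc table.
#' @return list with `node` (n x 36 orbit count matrix) and `graph`
#'   (named 16-class census).
#' @export
brute_triad_census <- function(x) {
  g <- as_graph(x, directed = TRUE)
  n <- g$n
  node <- matrix(0, n, 36, dimnames = list(g$nodes, paste0("o", 0:35)))
  graph <- stats::setNames(numeric(16), triad_class_names())
  if (n < 3) return(list(node = node, graph = graph))
  if (n > 60) stop("brute_triad_census: n > 60 is too large", call. = FALSE)
  ct <- code_orbit_int()
  ss <- utils::combn(n, 3)
  code <- code_of_triple(g, ss[1, ], ss[2, ], ss[3, ])
  orbs <- ct$orbits[code + 1, , drop = FALSE]
  node <- unclass(table(factor(as.vector(ss), seq_len(n)),
                        factor(as.vector(t(orbs)), 0:35)))
  storage.mode(node) <- "double"
  dimnames(node) <- list(g$nodes, paste0("o", 0:35))
  graph[] <- tabulate(ct$class[code + 1], nbins = 16)
  list(node = node, graph = graph)
}

#' Count isomorphism classes of small graphs by exhaustive canonicalisation
#'
#' `count_directed_quad_classes()` enumerates all 2^12 labelled 4-node
#' digraphs and reduces them under the 24 node permutations;
#' `count_quad_classes()` does the undirected analogue over 2^6 graphs, and
#' `count_triad_classes()` the 3-node directed analogue over the 64 dyad
#' codes.
#'
#' @return the number of isomorphism classes (218, 11 and 16 respectively).
#' @export
count_directed_quad_classes <- function() {
  pairs <- which(outer(1:4, 1:4, "!="), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), ]   # 12 ordered pairs
  perms <- perms_of(4)
  masks <- 0:4095
  bits <- matrix(0L, 4096, 12)
  for (k in 1:12) bits[, k] <- as.integer(bitwAnd(masks, 2^(k - 1)) > 0)
  pairkey <- pairs[, 1] * 10 + pairs[, 2]
  canon <- rep(Inf, 4096)
  for (p in seq_len(nrow(perms))) {
    pi <- perms[p, ]
    to <- match(pi[pairs[, 1]] * 10 + pi[pairs[, 2]], pairkey)
    newbits <- matrix(0L, 4096, 12)
    newbits[, to] <- bits
    canon <- pmin(canon, as.vector(newbits %*% 2^(0:11)))
  }
  length(unique(canon))
}

#' @rdname count_directed_quad_classes
#' @export
count_quad_classes <- function() {
  pp <- quad_pairs()
  perms <- perms_of(4)
  masks <- 0:63
  bits <- matrix(0L, 64, 6)
  for (k in 1:6) bits[, k] <- as.integer(bitwAnd(masks, 2^(k - 1)) > 0)
  pairkey <- pp[, 1] * 10 + pp[, 2]
  canon <- rep(Inf, 64)
  for (p in seq_len(nrow(perms))) {
    pi <- perms[p, ]
    a <- pmin(pi[pp[, 1]], pi[pp[, 2]])
    b <- pmax(pi[pp[, 1]], pi[pp[, 2]])
    to <- match(a * 10 + b, pairkey)
    newbits <- matrix(0L, 64, 6)
    newbits[, to] <- bits
    canon <- pmin(canon, as.vector(newbits %*% 2^(0:5)))
  }
  length(unique(canon))
}

#' @rdname count_directed_quad_classes
#' @export
count_triad_classes <- function() {
  length(unique(triad_canonical_codes()))
}

perms_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  out
}
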