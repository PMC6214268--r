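#' Synthetic graph generators
#'
#' Seeded, reproducible generators used as the package's test bed.
#'
#' `gen_small_world()` arranges `n` nodes on a ring, connects each to its
#' `r` nearest neighbours on each side, then rewires every lattice edge
#' independently with probability `p` to a uniformly random vacant non-self
#' dyad.
#'
#' `gen_pref_attach()` grows a network node by node; each new node attaches
#' to `r` distinct existing nodes, each chosen preferentially
#' (degree-proportional) or, with probability `p`, uniformly from the
#' current neighbours-of-neighbours of the new node (falling back to
#' preferential when that set is empty). The first `r + 1` nodes attach to
#' all earlier nodes, so `m = r n - choose(r + 1, 2)` exactly.
#'
#' `gen_gnp()` is the independent-edge model; for directed graphs each
#' ordered pair is an arc with probability `p`, and `reciprocation` is the
#' probability that each present arc additionally forces its reverse.
#'
#' @param n number of nodes.
#' @param r lattice half-width / attachments per node.
#' @param p rewiring / neighbour-bias / edge probability.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param directed generate a digraph (`gen_gnp` only).
#' @param reciprocation see above (`gen_gnp` only).
#' @return an `undirected_graph` (or `directed_graph`).
#' @examples
#' g <- gen_small_world(20, r = 2, p = 0, seed = 1)
#' quad_scan(g)$n_triangles
#' @name generators
NULL

#' @rdname generators
#' @export
gen_small_world <- function(n, r, p, seed = NULL) {
  stopifnot(n > 2 * r, r >= 1, p >= 0, p <= 1)
  targets <- unlist(lapply(1:r, function(k) ((seq_len(n) - 1 + k) %% n) + 1))
  em <- cbind(rep(seq_len(n), r), targets)
  a <- pmin(em[, 1], em[, 2])
  b <- pmax(em[, 1], em[, 2])
  with_local_seed(seed, {
    key <- (a - 1) * n + b
    present <- new.env(parent = emptyenv(), size = length(key))
    for (k in key) assign(as.character(k), TRUE, envir = present)
    rewire <- stats::runif(length(a)) < p
    for (i in which(rewire)) {
      repeat {
        x <- sample.int(n, 1)
        y <- sample.int(n, 1)
        if (x == y) next
        nk <- (min(x, y) - 1) * n + max(x, y)
        if (!exists(as.character(nk), envir = present, inherits = FALSE)) {
          rm(list = as.character((a[i] - 1) * n + b[i]), envir = present)
          assign(as.character(nk), TRUE, envir = present)
          a[i] <- min(x, y)
          b[i] <- max(x, y)
          break
        }
      }
    }
    undirected_graph(cbind(a, b), nodes = seq_len(n))
  })
}

#' @rdname generators
#' @export
gen_pref_attach <- function(n, r, p, seed = NULL) {
  stopifnot(n > r, r >= 1, p >= 0, p <= 1)
  with_local_seed(seed, {
    deg <- numeric(n)
    adj <- vector("list", n)
    from <- integer(0)
    to <- integer(0)
    for (v in 2:n) {
      k <- min(r, v - 1)
      chosen <- integer(0)
      if (k == v - 1) {
        chosen <- seq_len(v - 1)
      } else {
        for (j in seq_len(k)) {
          cand <- NULL
          if (stats::runif(1) < p && length(chosen)) {
            nn <- unique(unlist(adj[chosen]))
            nn <- setdiff(nn, c(v, chosen))
            if (length(nn)) cand <- nn[sample.int(length(nn), 1)]
          }
          if (is.null(cand)) {
            pool <- setdiff(seq_len(v - 1), chosen)
            cand <- pool[sample.int(length(pool), 1, prob = deg[pool])]
          }
          chosen <- c(chosen, cand)
        }
      }
      from <- c(from, rep(v, length(chosen)))
      to <- c(to, chosen)
      deg[v] <- deg[v] + length(chosen)
      deg[chosen] <- deg[chosen] + 1
      adj[[v]] <- c(adj[[v]], chosen)
      for (u in chosen) adj[[u]] <- c(adj[[u]], v)
    }
    undirected_graph(cbind(from, to), nodes = seq_len(n))
  })
}

#' @rdname generators
#' @export
gen_gnp <- function(n, p, seed = NULL, directed = FALSE, reciprocation = 0) {
  stopifnot(n >= 1, p >= 0, p <= 1, reciprocation >= 0, reciprocation <= 1)
  with_local_seed(seed, {
    if (!directed) {
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- stats::runif(nrow(pairs)) < p
      undirected_graph(pairs[keep, , drop = FALSE], nodes = seq_len(n))
    } else {
      pairs <- which(outer(seq_len(n), seq_len(n), "!="), arr.ind = TRUE)
      keep <- stats::runif(nrow(pairs)) < p
      arcs <- pairs[keep, , drop = FALSE]
      if (reciprocation > 0 && nrow(arcs)) {
        rec <- stats::runif(nrow(arcs)) < reciprocation
        arcs <- rbind(arcs, arcs[rec, 2:1, drop = FALSE])
      }
      directed_graph(arcs, nodes = seq_len(n))
    }
  })
}

#' Reverse every arc of a digraph
#'
#' @param g a `directed_graph`.
#' @return the `directed_graph` with all arcs reversed.
#' @export
reverse_graph <- function(g) {
  stopifnot(inherits(g, "directed_graph"))
  directed_graph(cbind(g$nodes[g$arcs[, 2]], g$nodes[g$arcs[, 1]]),
                 nodes = g$nodes)
}

#' Complement of an undirected graph
#'
#' @param g an `undirected_graph`.
#' @return the complement graph on the same nodes.
#' @export
complement_graph <- function(g) {
  stopifnot(inherits(g, "undirected_graph"))
  n <- g$n
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  key <- (all_pairs[, 1] - 1) * as.double(n) + all_pairs[, 2]
  ekey <- (g$edges[, 1] - 1) * as.double(n) + g$edges[, 2]
  keep <- !(key %in% ekey)
  ep <- all_pairs[keep, , drop = FALSE]
  undirected_graph(cbind(g$nodes[ep[, 1]], g$nodes[ep[, 2]]),
                   nodes = g$nodes)
}
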