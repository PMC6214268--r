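#' @name triad-orbits
#' @title Canonical triad classes and orbits
#'
#' @description
#' The 16 directed triad classes carry the standard M-A-N labels (counts of
#' mutual, asymmetric and null dyads, with D/U/C/T direction indicators).
#' Node orbits 0..35 are numbered in fixed blocks: 003 `{0}`, 012 `{1,2,3}`,
#' 102 `{4,5}`, 021C `{6,7,8}`, 021U `{9,10}`, 021D `{11,12}`, 111U
#' `{13,14,15}`, 111D `{16,17,18}`, 201 `{19,20}`, 030C `{21}`, 030T
#' `{22,23,24}`, 120U `{25,26}`, 120D `{27,28}`, 120C `{29,30,31}`, 210
#' `{32,33,34}`, 300 `{35}`; the 15 orbits 21..35 are exactly those of the
#' triads whose underlying graph is a triangle. Within a block, roles are
#' ordered by the ascending lexicographic key `(d_mutual, d_out, d_in)` of
#' the role in the class representative.
NULL

triad_class_names <- function() {
  c("003", "012", "102", "021D", "021U", "021C", "111D", "111U", "201",
    "030T", "030C", "120D", "120U", "120C", "210", "300")
}

triad_blocks <- function() {
  list("003" = 0L, "012" = 1:3, "102" = 4:5, "021C" = 6:8, "021U" = 9:10,
       "021D" = 11:12, "111U" = 13:15, "111D" = 16:18, "201" = 19:20,
       "030C" = 21L, "030T" = 22:24, "120U" = 25:26, "120D" = 27:28,
       "120C" = 29:31, "210" = 32:34, "300" = 35L)
}

# ordered node pairs of a triple (u, v, w) in dyad-code bit order:
# code = l(u,v) + 2 l(u,w) + 4 l(v,u) + 8 l(v,w) + 16 l(w,u) + 32 l(w,v)
triad_pairs <- function() {
  rbind(c(1L, 2L), c(1L, 3L), c(2L, 1L), c(2L, 3L), c(3L, 1L), c(3L, 2L))
}

# standard representatives of the 16 classes (arcs as (from, to) rows)
triad_representatives <- function() {
  list(
    "003"  = matrix(integer(0), 0, 2),
    "012"  = rbind(c(1L, 2L)),
    "102"  = rbind(c(1L, 2L), c(2L, 1L)),
    "021D" = rbind(c(2L, 1L), c(2L, 3L)),
    "021U" = rbind(c(1L, 2L), c(3L, 2L)),
    "021C" = rbind(c(1L, 2L), c(2L, 3L)),
    "111D" = rbind(c(1L, 2L), c(2L, 1L), c(3L, 2L)),
    "111U" = rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L)),
    "201"  = rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L)),
    "030T" = rbind(c(1L, 2L), c(3L, 2L), c(1L, 3L)),
    "030C" = rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L)),
    "120D" = rbind(c(2L, 1L), c(2L, 3L), c(1L, 3L), c(3L, 1L)),
    "120U" = rbind(c(1L, 2L), c(3L, 2L), c(1L, 3L), c(3L, 1L)),
    "120C" = rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L), c(3L, 1L)),
    "210"  = rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L), c(1L, 3L)),
    "300"  = rbind(c(1L, 2L), c(2L, 1L), c(1L, 3L), c(3L, 1L),
                   c(2L, 3L), c(3L, 2L))
  )
}

arcs_to_code <- function(arcs) {
  tp <- triad_pairs()
  key <- tp[, 1] * 10 + tp[, 2]
  if (nrow(arcs) == 0) return(0L)
  sum(2^(match(arcs[, 1] * 10 + arcs[, 2], key) - 1))
}

# 6 x 64 matrix: entry (p, code+1) is the code of the digraph after
# relabelling nodes by permutation p
triad_perm_codes <- function() {
  cache_get("triad_perm_codes", function() {
    tp <- triad_pairs()
    perms <- perms_of(3)
    key <- tp[, 1] * 10 + tp[, 2]
    bits <- matrix(0L, 64, 6)
    for (k in 1:6) bits[, k] <- as.integer(bitwAnd(0:63, 2^(k - 1)) > 0)
    pc <- matrix(0L, 6, 64)
    for (p in 1:6) {
      pi <- perms[p, ]
      to <- match(pi[tp[, 1]] * 10 + pi[tp[, 2]], key)
      newbits <- matrix(0L, 64, 6)
      newbits[, to] <- bits
      pc[p, ] <- as.integer(newbits %*% 2^(0:5))
    }
    pc
  })
}

triad_canonical_codes <- function() {
  pc <- triad_perm_codes()
  apply(pc, 2, min)
}

# internal frozen table: class id (position in triad_class_names()) and the
# 64 x 3 orbit matrix; generated programmatically and validated on build
code_orbit_int <- function() {
  cache_get("code_orbit_int", build_code_orbit_int)
}

build_code_orbit_int <- function() {
  pc <- triad_perm_codes()
  perms <- perms_of(3)
  canon <- apply(pc, 2, min)
  labels <- triad_class_names()
  reps <- triad_representatives()
  blocks <- triad_blocks()
  repcode <- vapply(reps, arcs_to_code, numeric(1))
  repcanon <- canon[repcode + 1]
  if (anyDuplicated(repcanon) || length(unique(canon)) != 16 ||
      !setequal(repcanon, unique(canon))) {
    stop("triad representatives do not cover the 16 classes", call. = FALSE)
  }

  orbit_of_rep <- list()
  for (lb in labels) {
    arcs <- reps[[lb]]
    code <- repcode[[lb]]
    auts <- which(pc[, code + 1] == code)
    orb_rep <- vapply(1:3, function(j) min(perms[auts, j]), integer(1))
    d_out <- tabulate(arcs[, 1], 3)
    d_in <- tabulate(arcs[, 2], 3)
    akey <- arcs[, 1] * 10 + arcs[, 2]
    d_mut <- vapply(1:3, function(j) {
      sum((arcs[, 1] == j) & ((arcs[, 2] * 10 + arcs[, 1]) %in% akey))
    }, numeric(1))
    reps_nodes <- sort(unique(orb_rep))
    keys <- cbind(d_mut[reps_nodes], d_out[reps_nodes], d_in[reps_nodes])
    ord <- order(keys[, 1], keys[, 2], keys[, 3])
    ids <- blocks[[lb]]
    if (length(ids) != length(reps_nodes)) {
      stop("orbit block size mismatch for triad ", lb, call. = FALSE)
    }
    orbit_id <- integer(3)
    for (r in seq_along(ord)) {
      orbit_id[orb_rep == reps_nodes[ord[r]]] <- ids[r]
    }
    orbit_of_rep[[lb]] <- orbit_id
  }

  class_id <- integer(64)
  orbits <- matrix(NA_integer_, 64, 3)
  for (code in 0:63) {
    lb <- labels[match(canon[code + 1], repcanon)]
    class_id[code + 1] <- match(lb, labels)
    p <- which(pc[, code + 1] == repcode[[lb]])[1]
    pi <- perms[p, ]
    orbits[code + 1, ] <- orbit_of_rep[[lb]][pi]
  }
  list(class = class_id, orbits = orbits)
}

#' The 64-entry dyad-code to triad/orbit lookup table
#'
#' Generated programmatically: the 64 labelled 3-node digraphs are reduced
#' to the 16 isomorphism classes by canonicalisation over all 6 node
#' permutations, node orbits are computed from each class's automorphism
#' group, and orbit integers are assigned by the canonical blocks (see
#' [triad-orbits]).
#'
#' @return a tibble with columns `code` (0..63), `triad` (M-A-N label) and
#'   `orbit_u`, `orbit_v`, `orbit_w`, the orbits of the three nodes of the
#'   ordered triple encoding `code`.
#' @examples
#' tab <- code_orbit_table()
#' tab[tab$code %in% c(0, 63), ]
#' @export
code_orbit_table <- function() {
  ct <- code_orbit_int()
  tibble::tibble(
    code = 0:63,
    triad = triad_class_names()[ct$class],
    orbit_u = ct$orbits[, 1],
    orbit_v = ct$orbits[, 2],
    orbit_w = ct$orbits[, 3]
  )
}

#' Dyad-pattern code of a node triple
#'
#' `code(u,v,w) = l(u,v) + 2 l(u,w) + 4 l(v,u) + 8 l(v,w) + 16 l(w,u) +
#' 32 l(w,v)` where `l(i,j)` is 1 when the arc `(i,j)` exists. Vectorised
#' over triples.
#'
#' @param g a `directed_graph`.
#' @param u,v,w node identifiers (character, matched against `g$nodes`) or
#'   internal integer indices; must be pairwise distinct.
#' @return integer vector of codes in 0..63.
#' @export
code_of_triple <- function(g, u, v, w) {
  stopifnot(inherits(g, "directed_graph"))
  ix <- function(x) {
    if (is.character(x)) {
      i <- match(x, g$nodes)
      if (anyNA(i)) stop("unknown node identifier", call. = FALSE)
      i
    } else as.integer(x)
  }
  u <- ix(u); v <- ix(v); w <- ix(w)
  if (any(u == v | u == w | v == w)) {
    stop("code_of_triple: nodes must be pairwise distinct", call. = FALSE)
  }
  n <- g$n
  l <- function(i, j) as.integer(keyed_lookup(g$arc_keys, (i - 1) * n + j))
  l(u, v) + 2L * l(u, w) + 4L * l(v, u) + 8L * l(v, w) +
    16L * l(w, u) + 32L * l(w, v)
}
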