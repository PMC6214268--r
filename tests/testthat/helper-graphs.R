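# fixture builders, all constructed in code

edges_k <- function(k) t(utils::combn(k, 2))          # complete graph K_k
edges_path <- function(k) cbind(1:(k - 1), 2:k)       # path on k nodes
edges_cycle <- function(k) rbind(cbind(1:(k - 1), 2:k), c(k, 1))
edges_star <- function(leaves) cbind(seq_len(leaves), leaves + 1L)

# paw: triangle a,b,c with pendant d on a
edges_paw <- function() {
  data.frame(u = c("a", "a", "b", "a"), v = c("b", "c", "c", "d"))
}

# diamond: K4 minus the edge {3,4}; degree-3 nodes are 1 and 2
edges_diamond <- function() rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4))

rand_undirected <- function(i, nmax = 30) {
  set.seed(i)
  n <- sample(5:nmax, 1)
  p <- stats::runif(1, 0.05, 0.9)
  gen_gnp(n, p, seed = 10000 + i)
}

rand_directed <- function(i, nmax = 25) {
  set.seed(i)
  n <- sample(4:nmax, 1)
  p <- stats::runif(1, 0.05, 0.6)
  rec <- sample(c(0, 0.3, 0.7), 1)
  gen_gnp(n, p, seed = 20000 + i, directed = TRUE, reciprocation = rec)
}

orbit_matrix <- function(tb) {
  as.matrix(tb[, grep("^o[0-9]+$", names(tb))])
}

# naive quadratic reference for the degeneracy (repeated min-degree removal)
naive_degeneracy <- function(g) {
  adj <- lapply(g$adj, identity)
  alive <- rep(TRUE, g$n)
  deg <- g$degree
  degeneracy <- 0L
  for (i in seq_len(g$n)) {
    cand <- which(alive)
    v <- cand[which.min(deg[cand])]
    degeneracy <- max(degeneracy, deg[v])
    alive[v] <- FALSE
    for (w in adj[[v]]) if (alive[w]) deg[w] <- deg[w] - 1L
  }
  degeneracy
}
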