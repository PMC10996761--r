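# Independent brute-force oracles: deliberately naive reimplementations
# (triple-loop Floyd-Warshall, explicit pair enumeration, 2^n sign
# enumeration) kept free of any package internals.

# all-pairs shortest paths by Floyd-Warshall on a length matrix
# (Inf = no edge)
oracle_floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_lengths <- function(adj) {
  len <- 1 / adj
  len[adj == 0] <- Inf
  diag(len) <- 0
  len
}

# mean finite shortest-path length over unordered pairs
oracle_cpl <- function(adj) {
  d <- oracle_floyd_warshall(oracle_lengths(adj))
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (length(v) == 0) NA_real_ else mean(v)
}

# mean inverse shortest-path length over pairs (disconnected -> 0)
oracle_ge <- function(adj) {
  if (nrow(adj) < 2) return(0)
  d <- oracle_floyd_warshall(oracle_lengths(adj))
  v <- 1 / d[upper.tri(d)]
  v[!is.finite(v)] <- 0
  mean(v)
}

# local efficiency: efficiency of the subgraph induced on the
# neighbours of node i, on adjacency normalized by the global max
oracle_le <- function(adj, i) {
  w <- adj
  if (max(w) > 0) w <- w / max(w)
  nbrs <- which(w[i, ] > 0)
  if (length(nbrs) < 2) return(0)
  oracle_ge(w[nbrs, nbrs, drop = FALSE])
}

# radius of a complete weighted graph: weights as lengths, min over
# nodes of the max shortest-path distance
oracle_radius <- function(w) {
  n <- nrow(w)
  if (n == 1) return(0)
  d <- oracle_floyd_warshall(w)
  min(apply(d, 1, max))
}

# exact two-sided signed-rank p by explicit enumeration of all 2^n
# sign assignments (ties get average ranks)
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# random symmetric adjacency with zero diagonal and a given edge density
random_adjacency <- function(n, density = 0.6) {
  adj <- matrix(0, n, n)
  m <- matrix(stats::runif(n * n), n)
  keep <- matrix(stats::runif(n * n) < density, n)
  up <- upper.tri(adj)
  adj[up] <- ifelse(keep[up], m[up], 0)
  adj <- adj + t(adj)
  adj
}

# package graph object wrapping a bare adjacency (unit coords/rates)
graph_from_adjacency <- function(adj) {
  n <- nrow(adj)
  nodes <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(nodes, nodes)
  len <- 1 / adj
  len[adj == 0] <- Inf
  diag(len) <- 0
  structure(list(nodes = nodes, adjacency = adj, lengths = len,
                 rates = stats::setNames(rep(1, n), nodes),
                 coords = matrix(stats::rnorm(n * 3), n, 3,
                                 dimnames = list(nodes, NULL)),
                 degenerate = n < 2,
                 disconnected = all(adj[upper.tri(adj)] == 0),
                 poor_sampling = FALSE),
            class = "fr_mi_graph")
}
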