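# Brute-force reference implementations of the six centrality measures,
# written against the adjacency matrix / igraph primitives so they share no
# code with the package's BFS/Brandes/power-iteration implementations.

adjMat <- function(g) igraph::as_adjacency_matrix(g, sparse = FALSE)

oracleDegree <- function(g) unname(rowSums(adjMat(g)))

oracleCloseness <- function(g) {
  D <- igraph::distances(g)
  n <- nrow(D)
  vapply(seq_len(n), function(v) {
    d <- D[v, ]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r <= 1L || n == 1L) return(0)
    (r - 1) / sum(d[reach]) * (r - 1) / (n - 1)
  }, numeric(1))
}

# exhaustive all-shortest-paths enumeration
oracleBetweenness <- function(g) {
  n <- igraph::vcount(g)
  bc <- numeric(n)
  if (n < 3L) return(bc)
  D <- igraph::distances(g)
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      if (!is.finite(D[s, t])) next
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t)$vpaths)
      k <- length(paths)
      for (p in paths) {
        interior <- setdiff(as.integer(p), c(s, t))
        bc[interior] <- bc[interior] + 1 / k
      }
    }
  }
  bc
}

# dense symmetric eigendecomposition on the largest component
oracleEigenvector <- function(g) {
  n <- igraph::vcount(g)
  out <- numeric(n)
  if (n == 0L) return(out)
  comp <- igraph::components(g)
  lcc <- which(comp$membership == which.max(comp$csize))
  if (length(lcc) == 1L) { out[lcc] <- 1; return(out) }
  A <- adjMat(g)[lcc, lcc]
  v <- eigen(A, symmetric = TRUE)$vectors[, 1L]
  out[lcc] <- abs(v)
  out
}

oracleLac <- function(g) {
  A <- adjMat(g)
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) == 0L) return(0)
    sum(A[nb, nb]) / length(nb)
  }, numeric(1))
}

oracleNetwork <- function(g) {
  A <- adjMat(g)
  A2 <- A %*% A            # A2[u, v] = common neighbours of u and v
  deg <- rowSums(A)
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] == 1)
    s <- 0
    for (u in nb) {
      denom <- min(deg[v] - 1, deg[u] - 1)
      if (denom > 0) s <- s + A2[v, u] / denom
    }
    s
  }, numeric(1))
}

randomConnectedGraph <- function(n, p = 0.5) {
  repeat {
    g <- igraph::sample_gnp(n, p, directed = FALSE)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
      return(g)
    }
  }
}

# exhaustive tail probability by enumerating every n-subset of 1..N with
# marked set 1..K: returns the matrix of P(X >= k) for k in 0..n rows not
# needed; helper for a single (k, n, K, N)
enumHyperTail <- function(k, n, K, N) {
  if (n == 0L) return(if (k == 0L) 1 else NA_real_)
  draws <- utils::combn(N, n)
  ov <- colSums(draws <= K)
  mean(ov >= k)
}
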