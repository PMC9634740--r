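# All six measures operate on a simple undirected igraph and return a
# numeric vector named by node. They are implemented from first principles
# (BFS, Brandes accumulation, shifted power iteration, triangle counting)
# because the median hub screen depends on their exact conventions:
# betweenness is raw (unnormalized, each unordered pair counted once),
# closeness is the component-size-corrected harmonic of distance sums, and
# eigenvector is the nonnegative unit-2-norm Perron vector.

checkGraph <- function(g) {
  stopifnot(inherits(g, "igraph"))
  if (igraph::is_directed(g)) stopf("graph must be undirected")
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    stopf("graph must be simple (no self-loops or multi-edges); see readEdgeList()")
  }
  invisible(g)
}

nodeNames <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  nm
}

adjIndexList <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

#' Degree centrality
#'
#' Number of neighbours of each node.
#'
#' @param g simple undirected igraph.
#' @return named numeric vector (integer-valued), one entry per node.
#' @family centrality measures
#' @export
degreeCentrality <- function(g) {
  checkGraph(g)
  stats::setNames(as.numeric(lengths(adjIndexList(g))), nodeNames(g))
}

bfsDistances <- function(adj, s, n) {
  dist <- rep.int(NA_integer_, n)
  dist[s] <- 0L
  queue <- integer(n); queue[1L] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (u in adj[[v]]) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        tail <- tail + 1L
        queue[tail] <- u
      }
    }
  }
  dist
}

#' Closeness centrality
#'
#' For a node `v` reaching `r` nodes (including itself) with total
#' shortest-path distance `S`, closeness is `(r - 1) / S` scaled by the
#' component-size correction `(r - 1) / (n - 1)`; on a connected graph the
#' correction is 1 and the value reduces to `(n - 1) / S`, which is 1 for a
#' node adjacent to everything. Isolated nodes get 0.
#'
#' @inheritParams degreeCentrality
#' @return named numeric vector in \[0, 1\].
#' @family centrality measures
#' @export
closenessCentrality <- function(g) {
  checkGraph(g)
  n <- igraph::vcount(g)
  adj <- adjIndexList(g)
  out <- numeric(n)
  for (v in seq_len(n)) {
    d <- bfsDistances(adj, v, n)
    reach <- which(!is.na(d))
    r <- length(reach)
    if (r <= 1L || n == 1L) { out[v] <- 0; next }
    S <- sum(d[reach])
    out[v] <- (r - 1) / S * (r - 1) / (n - 1)
  }
  stats::setNames(out, nodeNames(g))
}

#' Betweenness centrality
#'
#' Raw (unnormalized) shortest-path betweenness on an undirected graph:
#' for each unordered pair `{s, t}` (counted once), the fraction of
#' shortest s-t paths passing through `v`, accumulated by Brandes
#' single-source dependency stages. Endpoints are excluded.
#'
#' @inheritParams degreeCentrality
#' @return named non-negative numeric vector.
#' @family centrality measures
#' @export
betweennessCentrality <- function(g) {
  checkGraph(g)
  n <- igraph::vcount(g)
  adj <- adjIndexList(g)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # BFS stage: path counts sigma and predecessor lists
    dist <- rep.int(NA_integer_, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    dist[s] <- 0L; sigma[s] <- 1
    queue <- integer(n); queue[1L] <- s
    head <- 1L; tail <- 1L
    order_out <- integer(n); no <- 0L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      no <- no + 1L; order_out[no] <- v
      for (u in adj[[v]]) {
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + 1L
          tail <- tail + 1L; queue[tail] <- u
        }
        if (dist[u] == dist[v] + 1L) {
          sigma[u] <- sigma[u] + sigma[v]
          preds[[u]] <- c(preds[[u]], v)
        }
      }
    }
    # accumulation stage in reverse BFS order
    delta <- numeric(n)
    for (i in rev(seq_len(no))) {
      w <- order_out[i]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc / 2, nodeNames(g))   # each unordered pair counted once
}

#' Eigenvector centrality
#'
#' Principal (Perron) eigenvector of the adjacency matrix of the largest
#' connected component, nonnegative and normalized to unit Euclidean norm;
#' nodes outside that component get 0. Computed by power iteration on
#' `A + I` (the spectral shift leaves the eigenvector unchanged and
#' prevents oscillation on bipartite components) to relative tolerance
#' `tol`, erroring after `maxIter` sweeps without convergence.
#'
#' @inheritParams degreeCentrality
#' @param tol relative convergence tolerance (default 1e-10).
#' @param maxIter iteration cap (default 10000).
#' @return named non-negative numeric vector with unit 2-norm over the
#'   largest component.
#' @family centrality measures
#' @export
eigenvectorCentrality <- function(g, tol = 1e-10, maxIter = 10000L) {
  checkGraph(g)
  n <- igraph::vcount(g)
  out <- stats::setNames(numeric(n), nodeNames(g))
  if (n == 0L) return(out)
  comp <- igraph::components(g)
  lcc <- which(comp$membership == which.max(comp$csize))
  m <- length(lcc)
  if (m == 1L) { out[lcc] <- 1; return(out) }
  A <- matrix(0, m, m)
  el <- igraph::as_edgelist(g, names = FALSE)
  keep <- el[, 1L] %in% lcc & el[, 2L] %in% lcc
  el <- el[keep, , drop = FALSE]
  idx <- match(el, lcc); dim(idx) <- dim(el)
  A[idx] <- 1; A[idx[, c(2L, 1L), drop = FALSE]] <- 1
  x <- rep(1 / sqrt(m), m)
  for (it in seq_len(maxIter)) {
    y <- as.numeric(A %*% x) + x          # (A + I) x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) <= tol * max(abs(y))) {
      out[lcc] <- abs(y)
      return(out)
    }
    x <- y
  }
  stopf("power iteration did not reach relative tolerance %g in %d iterations",
        tol, maxIter)
}

#' Local average connectivity (LAC)
#'
#' Mean degree of a node's neighbours within the subgraph induced on those
#' neighbours: `LAC(v) = sum_u deg_{G[N(v)]}(u) / |N(v)|`. Zero for nodes
#' of degree 0 or 1 (no neighbour pair can be connected). Bounded above by
#' `deg(v) - 1`.
#'
#' @inheritParams degreeCentrality
#' @return named non-negative numeric vector.
#' @family centrality measures
#' @export
lacCentrality <- function(g) {
  checkGraph(g)
  n <- igraph::vcount(g)
  adj <- adjIndexList(g)
  inN <- logical(n)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    d <- length(nb)
    if (d == 0L) next
    inN[nb] <- TRUE
    tot <- 0L
    for (u in nb) tot <- tot + sum(inN[adj[[u]]])
    inN[nb] <- FALSE
    out[v] <- tot / d
  }
  stats::setNames(out, nodeNames(g))
}

#' Network centrality (summed edge clustering coefficients)
#'
#' For each incident edge `{v, u}`, the edge clustering coefficient is
#' `ECC(v, u) = z / min(deg(v) - 1, deg(u) - 1)` where `z` is the number of
#' triangles containing the edge (common neighbours of `v` and `u`); ECC is
#' 0 when the denominator is 0. `NC(v)` is the sum of ECC over the edges at
#' `v`, bounded above by `deg(v)`.
#'
#' @inheritParams degreeCentrality
#' @return named non-negative numeric vector.
#' @family centrality measures
#' @export
networkCentrality <- function(g) {
  checkGraph(g)
  n <- igraph::vcount(g)
  adj <- adjIndexList(g)
  deg <- lengths(adj)
  inN <- logical(n)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) == 0L) next
    inN[nb] <- TRUE
    nc <- 0
    for (u in nb) {
      denom <- min(deg[v] - 1L, deg[u] - 1L)
      if (denom > 0L) {
        z <- sum(inN[adj[[u]]])   # common neighbours of v and u
        nc <- nc + z / denom
      }
    }
    inN[nb] <- FALSE
    out[v] <- nc
  }
  stats::setNames(out, nodeNames(g))
}

#' All six centralities as one table
#'
#' Computes betweenness, closeness, degree, eigenvector, LAC and network
#' centrality for every node, in the column order conventionally reported
#' for PPI hub screening.
#'
#' @inheritParams degreeCentrality
#' @return data.frame with columns `name`, `betweenness`, `closeness`,
#'   `degree`, `eigenvector`, `lac`, `network`, one row per node in graph
#'   vertex order.
#' @export
centralityTable <- function(g) {
  checkGraph(g)
  data.frame(
    name = nodeNames(g),
    betweenness = unname(betweennessCentrality(g)),
    closeness = unname(closenessCentrality(g)),
    degree = unname(degreeCentrality(g)),
    eigenvector = unname(eigenvectorCentrality(g)),
    lac = unname(lacCentrality(g)),
    network = unname(networkCentrality(g)),
    stringsAsFactors = FALSE)
}
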