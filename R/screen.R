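#' Iterative median hub screen on a PPI graph
#'
#' The core-target selection procedure: in each round, compute all six
#' centrality measures on the current graph, take each measure's median
#' over the current nodes (standard order-statistic median, i.e. the mean
#' of the two middle values for even n), and retain the nodes whose six
#' values are ALL greater than or equal to their medians (retention is
#' inclusive, so nodes sitting exactly on a threshold survive). The
#' subgraph induced on the survivors enters the next round. Two rounds is
#' the conventional depth for extracting a hub subnetwork from a
#' ~100-node high-confidence PPI graph.
#'
#' A round with zero survivors stops the screen early; the result flags it.
#'
#' @param g simple undirected igraph (non-empty).
#' @param rounds number of filtering rounds (default 2).
#' @param verbose log per-round survivor counts to `message()`.
#' @return a [MedianScreen-class]; see [survivors()], [thresholds()],
#'   [hubSubgraph()].
#' @examples
#' g <- hubExampleGraph()
#' scr <- medianScreen(g, rounds = 2)
#' survivors(scr)
#' @export
medianScreen <- function(g, rounds = 2L, verbose = FALSE) {
  checkGraph(g)
  if (igraph::vcount(g) == 0L) stopf("medianScreen() needs a non-empty graph")
  stopifnot(rounds >= 1L)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  cur <- g
  res <- list()
  stopped <- FALSE
  for (r in seq_len(rounds)) {
    tab <- centralityTable(cur)
    med <- vapply(CENTRALITY_MEASURES, function(mm) stats::median(tab[[mm]]),
                  numeric(1))
    keep <- rep(TRUE, nrow(tab))
    for (mm in CENTRALITY_MEASURES) keep <- keep & tab[[mm]] >= med[[mm]]
    if (!any(keep)) {
      stopped <- TRUE
      if (verbose) message(sprintf("round %d: no survivors; stopping early", r))
      break
    }
    kept <- tab[keep, , drop = FALSE]
    kept <- kept[order(-kept$degree, kept$name), , drop = FALSE]
    sub <- igraph::induced_subgraph(cur, kept$name)
    res[[r]] <- new("ScreenRound", roundIndex = as.integer(r),
                    thresholds = med, survivors = kept$name, subgraph = sub)
    if (verbose) {
      message(sprintf("round %d: %d of %d nodes retained", r,
                      nrow(kept), nrow(tab)))
    }
    cur <- sub
  }
  new("MedianScreen", graph = g, rounds = res, stoppedEarly = stopped)
}

#' Bipartite compound-target network
#'
#' One node per compound and per target gene, one edge per
#' (compound, target) pair; node roles are tagged in the `type` vertex
#' attribute (`"compound"` / `"target"`). A compound's degree in this graph
#' counts the disease-relevant genes it hits, the usual ranking for
#' selecting representative active components.
#'
#' @param perCompoundTargets named list of [GeneSet-class] target sets per
#'   compound, typically the `perCompound` element of
#'   [intersectDrugDisease()]; compounds with empty sets become isolated
#'   compound nodes.
#' @return an undirected bipartite igraph.
#' @export
buildBipartite <- function(perCompoundTargets) {
  stopifnot(is.list(perCompoundTargets),
            all(vapply(perCompoundTargets, is, logical(1), "GeneSet")))
  cmp <- names(perCompoundTargets)
  if (is.null(cmp)) cmp <- vapply(perCompoundTargets, setName, character(1))
  tgt <- unique(unlist(lapply(perCompoundTargets, genes), use.names = FALSE))
  clash <- intersect(cmp, tgt)
  if (length(clash)) {
    stopf("node id(s) used both as compound and target: %s",
          paste(utils::head(clash, 5L), collapse = ", "))
  }
  edges <- do.call(rbind, lapply(seq_along(perCompoundTargets), function(i) {
    gset <- genes(perCompoundTargets[[i]])
    if (length(gset) == 0L) return(NULL)
    cbind(cmp[i], gset)
  }))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(cmp), name = cmp, type = "compound")
  g <- igraph::add_vertices(g, length(tgt), name = tgt, type = "target")
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::simplify(g)
}

#' A conforming 11-node hub subnetwork
#'
#' Deterministically constructs an 11-node, 45-edge connected graph with
#' one universal node (adjacent to all others) and degree sequence
#' 10, 9, 9, 9, 9, 8, 8, 7, 7, 7, 7: the non-universal nodes carry the
#' complete graph K10 minus a fixed 10-edge complement realising that
#' sequence. Useful as a worked example for the centrality measures: the
#' universal node has closeness 1, LAC `2 * (45 - 10) / 10 = 7` and network
#' centrality equal to its degree (every incident edge closes its maximum
#' number of triangles), while nodes of degree 9, 8 and 7 have closeness
#' 10/11, 10/12 and 10/13.
#'
#' @param labels optional character vector of 11 node names; the first is
#'   the universal node.
#' @return an undirected igraph with 11 nodes and 45 edges.
#' @examples
#' g <- hubExampleGraph()
#' igraph::ecount(g)
#' lacCentrality(g)[["H01"]]
#' @export
hubExampleGraph <- function(labels = sprintf("H%02d", 1:11)) {
  stopifnot(length(labels) == 11L, !anyDuplicated(labels))
  u <- labels[1L]
  rest <- labels[2:11]
  # complement (within K10) with degree sequence 1,1,1,1,2,2,3,3,3,3:
  # nodes 1..4 lose one edge, 5..6 lose two, 7..10 pairwise complete
  missing <- rbind(
    c(7L, 8L), c(7L, 9L), c(7L, 10L), c(8L, 9L), c(8L, 10L), c(9L, 10L),
    c(5L, 6L), c(5L, 1L), c(6L, 2L), c(3L, 4L))
  full <- t(utils::combn(10L, 2L))
  keyFull <- full[, 1L] * 100L + full[, 2L]
  keyMiss <- pmin(missing[, 1L], missing[, 2L]) * 100L +
    pmax(missing[, 1L], missing[, 2L])
  inner <- full[!(keyFull %in% keyMiss), , drop = FALSE]
  edges <- rbind(cbind(u, rest),
                 cbind(rest[inner[, 1L]], rest[inner[, 2L]]))
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = labels))
}
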