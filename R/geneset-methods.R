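#' @rdname netpharm-accessors
#' @export
setMethod("genes", "GeneSet", function(x, ...) x@genes)

#' @rdname netpharm-accessors
#' @export
setMethod("setName", "GeneSet", function(x, ...) x@name)

#' @describeIn GeneSet-class number of genes in the set.
#' @param x a `GeneSet`.
#' @export
setMethod("length", "GeneSet", function(x) length(x@genes))

setMethod("show", "GeneSet", function(object) {
  g <- object@genes
  preview <- paste(utils::head(g, 6L), collapse = ", ")
  if (length(g) > 6L) preview <- paste0(preview, ", ...")
  cat(sprintf("GeneSet '%s' with %d gene(s)%s\n",
              object@name, length(g),
              if (length(g)) paste0(": ", preview) else ""))
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig\n")
  cat(sprintf("  seed: %d\n", object@seed))
  cat(sprintf("  compounds: %d (OB ~ N(%.2f, %.2f) | DL ~ N(%.3f, %.3f); target pass %.2f)\n",
              object@nCompounds, object@obMean, object@obSd,
              object@dlMean, object@dlSd, object@fracPass))
  cat(sprintf("  disease sources: %d of sizes %s over a %d-gene universe (Jaccard ~ %.2f)\n",
              object@nSources, paste(object@sourceSizes, collapse = "/"),
              object@nUniverse, object@pairwiseOverlap))
  cat(sprintf("  annotation: %d terms (%d planted enriched, strength %.1f)\n",
              object@nTerms, object@nEnrichedTerms, object@enrichmentStrength))
  cat(sprintf("  PPI: %d nodes, edge prob %.3f, %d planted hubs (+%d edges each)\n",
              object@ppiNodes, object@ppiEdgeProb, object@nHubs,
              object@hubDegreeBoost))
})

#' @rdname netpharm-accessors
#' @param round round number; defaults to the final round.
#' @export
setMethod("survivors", "MedianScreen", function(x, round = nRounds(x), ...) {
  if (nRounds(x) == 0L) return(character())
  x@rounds[[round]]@survivors
})

#' @rdname netpharm-accessors
#' @export
setMethod("thresholds", "MedianScreen", function(x, round = nRounds(x), ...) {
  x@rounds[[round]]@thresholds
})

#' @rdname netpharm-accessors
#' @export
setMethod("nRounds", "MedianScreen", function(x) length(x@rounds))

#' @describeIn MedianScreen-class the induced subgraph of a round's
#'   survivors (defaults to the final round).
#' @param x a `MedianScreen`.
#' @param round round number.
#' @export
hubSubgraph <- function(x, round = nRounds(x)) {
  stopifnot(is(x, "MedianScreen"))
  if (nRounds(x) == 0L) return(igraph::make_empty_graph(directed = FALSE))
  x@rounds[[round]]@subgraph
}

setMethod("show", "MedianScreen", function(object) {
  cat(sprintf("MedianScreen: %d node(s) in, %d round(s)%s\n",
              igraph::vcount(object@graph), nRounds(object),
              if (object@stoppedEarly) " (stopped early: empty round)" else ""))
  for (r in object@rounds) {
    cat(sprintf("  round %d: %d survivor(s); medians [%s]\n",
                r@roundIndex, length(r@survivors),
                paste(sprintf("%s=%.4g", names(r@thresholds), r@thresholds),
                      collapse = ", ")))
  }
  if (nRounds(object) > 0L) {
    fin <- survivors(object)
    cat(sprintf("  hubs: %s\n", paste(utils::head(fin, 12L), collapse = ", ")))
  }
})
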