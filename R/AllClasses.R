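#' @import methods
NULL

setOldClass("igraph")

#' GeneSet: a named, normalized set of gene symbols
#'
#' The shared currency of the pipeline: disease-source gene lists, drug
#' target sets and annotation terms are all `GeneSet` objects. Symbols are
#' normalized on construction (trimmed, upper-cased, deduplicated, empties
#' dropped); no alias resolution is attempted.
#'
#' @slot name single character label for the set.
#' @slot genes character vector of normalized, unique gene symbols.
#'
#' @examples
#' gs <- GeneSet(c("jun", " Jun", "TP53"), name = "demo")
#' genes(gs)
#' length(gs)
#' @aliases GeneSet-class
#' @export
setClass("GeneSet", representation(name = "character", genes = "character"))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
  g <- object@genes
  if (anyNA(g)) msg <- c(msg, "gene symbols must not be NA")
  if (any(g != toupper(trimws(g)))) {
    msg <- c(msg, "gene symbols must be trimmed and upper-case")
  }
  if (anyDuplicated(g)) msg <- c(msg, "gene symbols must be unique")
  if (any(!nzchar(g))) msg <- c(msg, "gene symbols must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @param genes character vector of gene symbols (normalized on construction).
#' @param name label for the set.
#' @rdname GeneSet-class
#' @export
GeneSet <- function(genes = character(), name = "") {
  g <- toupper(trimws(as.character(genes)))
  g <- unique(g[!is.na(g) & nzchar(g)])
  new("GeneSet", name = as.character(name), genes = g)
}

#' SynthConfig: parameters of the synthetic input generator
#'
#' One object parameterizes every generator (`genCompounds()`,
#' `genDiseaseSources()`, `genDrugTargets()`, `genAnnotation()`, `genPpi()`,
#' `genDockingMatrix()`). A single integer `seed` drives a named RNG
#' sub-stream per generator, so regenerating one input never perturbs the
#' others. Defaults emulate the scale of a typical single-herb
#' network-pharmacology study: a TCMSP-sized compound table, four partially
#' overlapping disease-gene sources, and a 117-node high-confidence PPI
#' graph whose mean degree matches a STRING export at the 0.900 confidence
#' cutoff.
#'
#' The compound generator draws oral bioavailability (OB, percent) from a
#' normal truncated at 0 and drug-likeness (DL) from a normal clamped to
#' [0, 1]; when `obMean`/`dlMean` are `NA` they are placed so each axis
#' clears its ADMET cutoff (OB >= 30, DL >= 0.18) with probability
#' `sqrt(fracPass)`, making the joint expected pass fraction exactly
#' `fracPass`.
#'
#' @slot seed integer master seed.
#' @slot nCompounds number of compounds to draw.
#' @slot obMean,obSd OB distribution (percent); `obMean = NA` derives it
#'   from `fracPass`.
#' @slot dlMean,dlSd DL distribution (unitless); `dlMean = NA` derives it
#'   from `fracPass`.
#' @slot fracPass target fraction of compounds passing the joint ADMET filter.
#' @slot nUniverse gene-universe size.
#' @slot nSources number of disease-gene sources.
#' @slot sourceSizes integer sizes of each source list.
#' @slot pairwiseOverlap target pairwise Jaccard overlap between sources,
#'   realised by a shared core.
#' @slot targetsPerCompound length-2 integer range of targets per compound.
#' @slot targetDiseaseFrac fraction of each compound's targets drawn from
#'   the disease union (guarantees a non-empty drug-disease intersection).
#' @slot nTerms number of annotation terms.
#' @slot termSizeRange length-2 integer range of term sizes.
#' @slot nEnrichedTerms number of terms planted enriched for the signal set.
#' @slot enrichmentStrength sampling-odds multiplier (> 1) for signal genes
#'   in planted terms.
#' @slot ppiNodes number of PPI nodes.
#' @slot ppiEdgeProb Erdos-Renyi backbone edge probability.
#' @slot nHubs number of planted hubs.
#' @slot hubDegreeBoost extra random neighbours wired to each planted hub.
#' @slot hubCliqueProb probability that each pair of planted hubs is
#'   connected, forming the dense hub community characteristic of PPI hub
#'   modules (default 0.8, the density observed in published hub
#'   subnetworks of this size).
#'
#' @examples
#' cfg <- synthConfig(seed = 7)
#' cfg
#' @aliases SynthConfig-class
#' @export
setClass("SynthConfig", representation(
  seed = "integer",
  nCompounds = "integer",
  obMean = "numeric", obSd = "numeric",
  dlMean = "numeric", dlSd = "numeric",
  fracPass = "numeric",
  nUniverse = "integer",
  nSources = "integer",
  sourceSizes = "integer",
  pairwiseOverlap = "numeric",
  targetsPerCompound = "integer",
  targetDiseaseFrac = "numeric",
  nTerms = "integer",
  termSizeRange = "integer",
  nEnrichedTerms = "integer",
  enrichmentStrength = "numeric",
  ppiNodes = "integer",
  ppiEdgeProb = "numeric",
  nHubs = "integer",
  hubDegreeBoost = "integer",
  hubCliqueProb = "numeric"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  chkProb <- function(x, nm) {
    if (any(x < 0 | x > 1)) c(sprintf("'%s' must lie in [0, 1]", nm)) else character()
  }
  chkPos <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0)) c(sprintf("'%s' must be non-negative", nm)) else character()
  }
  msg <- c(msg,
    chkPos(object@nCompounds, "nCompounds"),
    chkPos(object@nUniverse, "nUniverse"),
    chkPos(object@nSources, "nSources"),
    chkPos(object@sourceSizes, "sourceSizes"),
    chkPos(object@nTerms, "nTerms"),
    chkPos(object@nEnrichedTerms, "nEnrichedTerms"),
    chkPos(object@ppiNodes, "ppiNodes"),
    chkPos(object@nHubs, "nHubs"),
    chkPos(object@hubDegreeBoost, "hubDegreeBoost"),
    chkProb(object@fracPass, "fracPass"),
    chkProb(object@pairwiseOverlap, "pairwiseOverlap"),
    chkProb(object@targetDiseaseFrac, "targetDiseaseFrac"),
    chkProb(object@ppiEdgeProb, "ppiEdgeProb"),
    chkProb(object@hubCliqueProb, "hubCliqueProb"))
  if (length(object@sourceSizes) != object@nSources) {
    msg <- c(msg, "'sourceSizes' must have length 'nSources'")
  }
  if (length(object@targetsPerCompound) != 2L ||
      any(diff(object@targetsPerCompound) < 0)) {
    msg <- c(msg, "'targetsPerCompound' must be a non-decreasing length-2 range")
  }
  if (length(object@termSizeRange) != 2L || any(diff(object@termSizeRange) < 0)) {
    msg <- c(msg, "'termSizeRange' must be a non-decreasing length-2 range")
  }
  if (object@enrichmentStrength < 1) {
    msg <- c(msg, "'enrichmentStrength' must be >= 1")
  }
  if (object@nEnrichedTerms > object@nTerms) {
    msg <- c(msg, "'nEnrichedTerms' must not exceed 'nTerms'")
  }
  if (object@nHubs > object@ppiNodes) {
    msg <- c(msg, "'nHubs' must not exceed 'ppiNodes'")
  }
  if (length(msg)) msg else TRUE
})

#' @param seed,nCompounds,obMean,obSd,dlMean,dlSd,fracPass,nUniverse,nSources
#'   see slots.
#' @param sourceSizes,pairwiseOverlap,targetsPerCompound,targetDiseaseFrac
#'   see slots.
#' @param nTerms,termSizeRange,nEnrichedTerms,enrichmentStrength see slots.
#' @param ppiNodes,ppiEdgeProb,nHubs,hubDegreeBoost,hubCliqueProb see slots.
#' @rdname SynthConfig-class
#' @export
synthConfig <- function(seed = 1L,
                        nCompounds = 500L,
                        obMean = NA_real_, obSd = 15,
                        dlMean = NA_real_, dlSd = 0.15,
                        fracPass = 0.5,
                        nUniverse = 5000L,
                        nSources = 4L,
                        sourceSizes = c(1500L, 600L, 300L, 150L),
                        pairwiseOverlap = 0.15,
                        targetsPerCompound = c(5L, 40L),
                        targetDiseaseFrac = 0.4,
                        nTerms = 200L,
                        termSizeRange = c(20L, 100L),
                        nEnrichedTerms = 5L,
                        enrichmentStrength = 8,
                        ppiNodes = 117L,
                        ppiEdgeProb = 0.035,
                        nHubs = 11L,
                        hubDegreeBoost = 20L,
                        hubCliqueProb = 0.8) {
  # place each marginal so the joint ADMET pass probability is fracPass
  if (is.na(obMean)) {
    obMean <- OB_MIN_DEFAULT - obSd * stats::qnorm(1 - sqrt(fracPass))
  }
  if (is.na(dlMean)) {
    dlMean <- DL_MIN_DEFAULT - dlSd * stats::qnorm(1 - sqrt(fracPass))
  }
  new("SynthConfig",
      seed = as.integer(seed),
      nCompounds = as.integer(nCompounds),
      obMean = obMean, obSd = obSd, dlMean = dlMean, dlSd = dlSd,
      fracPass = fracPass,
      nUniverse = as.integer(nUniverse),
      nSources = as.integer(nSources),
      sourceSizes = as.integer(sourceSizes),
      pairwiseOverlap = pairwiseOverlap,
      targetsPerCompound = as.integer(targetsPerCompound),
      targetDiseaseFrac = targetDiseaseFrac,
      nTerms = as.integer(nTerms),
      termSizeRange = as.integer(termSizeRange),
      nEnrichedTerms = as.integer(nEnrichedTerms),
      enrichmentStrength = enrichmentStrength,
      ppiNodes = as.integer(ppiNodes),
      ppiEdgeProb = ppiEdgeProb,
      nHubs = as.integer(nHubs),
      hubDegreeBoost = as.integer(hubDegreeBoost),
      hubCliqueProb = hubCliqueProb)
}

#' ScreenRound: one round of the iterative median hub screen
#'
#' @slot roundIndex 1-based round number.
#' @slot thresholds named numeric of the six per-measure medians applied
#'   in this round (computed on the graph entering the round).
#' @slot survivors node ids retained (all six centralities >= their
#'   medians), ordered by degree descending then name.
#' @slot subgraph igraph induced on the survivors.
#'
#' @aliases ScreenRound-class
#' @export
setClass("ScreenRound", representation(
  roundIndex = "integer",
  thresholds = "numeric",
  survivors = "character",
  subgraph = "igraph"
))

setValidity("ScreenRound", function(object) {
  msg <- character()
  if (object@roundIndex < 1L) msg <- c(msg, "'roundIndex' must be >= 1")
  if (!setequal(names(object@thresholds), CENTRALITY_MEASURES)) {
    msg <- c(msg, "'thresholds' must be named by the six centrality measures")
  }
  if (!setequal(object@survivors, igraph::V(object@subgraph)$name)) {
    msg <- c(msg, "'subgraph' nodes must equal the survivors")
  }
  if (length(msg)) msg else TRUE
})

#' MedianScreen: result of the iterative median hub screen
#'
#' Returned by [medianScreen()]. Holds the input graph and one
#' [ScreenRound-class] per completed round; `survivors()` with no round
#' argument gives the final hub set.
#'
#' @slot graph the input igraph.
#' @slot rounds list of [ScreenRound-class] objects.
#' @slot stoppedEarly TRUE when a round produced zero survivors and the
#'   screen stopped before the requested number of rounds.
#'
#' @aliases MedianScreen-class
#' @export
setClass("MedianScreen", representation(
  graph = "igraph",
  rounds = "list",
  stoppedEarly = "logical"
))

setValidity("MedianScreen", function(object) {
  if (!all(vapply(object@rounds, is, logical(1), "ScreenRound"))) {
    return("'rounds' must be a list of ScreenRound objects")
  }
  surv <- lapply(object@rounds, slot, "survivors")
  if (length(surv) > 1L) {
    for (i in seq_along(surv)[-1L]) {
      if (!all(surv[[i]] %in% surv[[i - 1L]])) {
        return("survivors must be nested across rounds")
      }
    }
  }
  TRUE
})
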