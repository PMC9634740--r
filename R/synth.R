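# Synthetic input generators. Each generator draws from its own named RNG
# sub-stream of the config seed (see subSeed()), so outputs are
# byte-identical under a fixed config and independent across generators.

#' @describeIn synthConfig the synthetic gene universe (symbols G00001...).
#' @param cfg a [SynthConfig-class].
#' @export
universeGenes <- function(cfg) {
  GeneSet(sprintf("G%05d", seq_len(cfg@nUniverse)), name = "universe")
}

#' Generate a synthetic compound property table
#'
#' Draws `nCompounds` compounds with OB ~ Normal(`obMean`, `obSd`) truncated
#' at 0 and DL ~ Normal(`dlMean`, `dlSd`) clamped to \[0, 1\]. With the
#' default config the means are placed so the joint ADMET filter
#' (OB >= 30, DL >= 0.18) passes an expected fraction `fracPass` of
#' compounds. Values are printed to table precision (OB 2 dp, DL 3 dp).
#'
#' @param cfg a [SynthConfig-class].
#' @return data.frame in [readCompoundTable()] layout.
#' @export
genCompounds <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  n <- cfg@nCompounds
  if (n == 0L) {
    return(data.frame(molId = character(), name = character(),
                      ob = numeric(), dl = numeric(),
                      stringsAsFactors = FALSE))
  }
  withSubSeed(cfg@seed, "compounds", {
    ob <- round(pmax(stats::rnorm(n, cfg@obMean, cfg@obSd), 0), 2)
    dl <- round(pmin(pmax(stats::rnorm(n, cfg@dlMean, cfg@dlSd), 0), 1), 3)
    data.frame(molId = sprintf("SYN%05d", seq_len(n)),
               name = sprintf("compound_%04d", seq_len(n)),
               ob = ob, dl = dl, stringsAsFactors = FALSE)
  })
}

#' Generate partially overlapping disease-gene sources
#'
#' Emulates querying several disease-gene databases: `nSources` sets over
#' the synthetic universe, sharing a common core sized so the pairwise
#' Jaccard index is approximately `pairwiseOverlap`
#' (`core = 2 * sbar * J / (1 + J)` for mean source size `sbar`), with the
#' remainder of each source drawn independently.
#'
#' @param cfg a [SynthConfig-class].
#' @return named list of [GeneSet-class]s (`SRC1`, `SRC2`, ...).
#' @export
genDiseaseSources <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  uni <- genes(universeGenes(cfg))
  sizes <- cfg@sourceSizes
  J <- cfg@pairwiseOverlap
  coreSize <- min(round(2 * mean(sizes) * J / (1 + J)), min(sizes))
  withSubSeed(cfg@seed, "disease-sources", {
    core <- sample(uni, coreSize)
    rest <- setdiff(uni, core)
    out <- vector("list", cfg@nSources)
    for (i in seq_len(cfg@nSources)) {
      extra <- sample(rest, sizes[i] - coreSize)
      out[[i]] <- GeneSet(c(core, extra), name = sprintf("SRC%d", i))
    }
    names(out) <- vapply(out, setName, character(1))
    out
  })
}

#' Generate per-compound target sets
#'
#' Each compound receives a target set whose size is uniform in
#' `targetsPerCompound`; a fraction `targetDiseaseFrac` of the targets is
#' drawn from the disease union (so the drug-disease intersection is
#' non-empty by construction) and the rest from the remainder of the
#' universe.
#'
#' @param cfg a [SynthConfig-class].
#' @param compounds data.frame of compounds (only `molId` is used).
#' @param diseaseUnion [GeneSet-class] of disease genes.
#' @return named list of [GeneSet-class] target sets, one per compound.
#' @export
genDrugTargets <- function(cfg, compounds, diseaseUnion) {
  stopifnot(is(cfg, "SynthConfig"), is.data.frame(compounds),
            is(diseaseUnion, "GeneSet"))
  uni <- genes(universeGenes(cfg))
  dis <- intersect(genes(diseaseUnion), uni)
  nondis <- setdiff(uni, dis)
  rng <- cfg@targetsPerCompound
  withSubSeed(cfg@seed, "drug-targets", {
    out <- lapply(compounds$molId, function(id) {
      size <- sample(seq.int(rng[1L], rng[2L]), 1L)
      nd <- min(round(size * cfg@targetDiseaseFrac), length(dis))
      GeneSet(c(sample(dis, nd), sample(nondis, size - nd)), name = id)
    })
    names(out) <- compounds$molId
    out
  })
}

#' Generate annotation terms with planted enrichment
#'
#' Draws `nTerms` annotation sets over the universe with sizes uniform in
#' `termSizeRange`. The first `nEnrichedTerms` terms sample the
#' `signalGenes` with odds multiplied by `enrichmentStrength`, planting
#' recoverable enrichment for a query equal to (or overlapping) the signal
#' set; the remaining terms sample uniformly. Categories cycle through
#' BP/CC/MF/KEGG so per-category reporting is exercised.
#'
#' @param cfg a [SynthConfig-class].
#' @param signalGenes [GeneSet-class] the planted terms oversample.
#' @param universe optional [GeneSet-class]; defaults to the synthetic
#'   universe.
#' @return list with `terms` (named list of [GeneSet-class]s), `planted`
#'   (names of the enriched terms) and `categories` (character vector
#'   aligned with `terms`).
#' @export
genAnnotation <- function(cfg, signalGenes, universe = universeGenes(cfg)) {
  stopifnot(is(cfg, "SynthConfig"), is(signalGenes, "GeneSet"),
            is(universe, "GeneSet"))
  uni <- genes(universe)
  w <- rep(1, length(uni))
  w[uni %in% genes(signalGenes)] <- cfg@enrichmentStrength
  rng <- cfg@termSizeRange
  cats <- rep_len(c("BP", "CC", "MF", "KEGG"), cfg@nTerms)
  withSubSeed(cfg@seed, "annotation", {
    terms <- vector("list", cfg@nTerms)
    for (i in seq_len(cfg@nTerms)) {
      size <- sample(seq.int(rng[1L], rng[2L]), 1L)
      planted <- i <= cfg@nEnrichedTerms
      memb <- sample(uni, size, prob = if (planted) w else NULL)
      nm <- if (planted) sprintf("TERM_PLANTED_%02d", i)
            else sprintf("TERM_%04d", i)
      terms[[i]] <- GeneSet(memb, name = nm)
    }
    names(terms) <- vapply(terms, setName, character(1))
    list(terms = terms,
         planted = names(terms)[seq_len(cfg@nEnrichedTerms)],
         categories = cats)
  })
}

#' Generate a PPI graph with planted hubs
#'
#' Erdos-Renyi backbone `G(n, ppiEdgeProb)` over the given nodes, after
#' which `nHubs` randomly chosen nodes are planted as a hub module: each
#' hub pair is connected with probability `hubCliqueProb` (hub modules in
#' real PPI networks are densely interconnected, and the triangle-based
#' measures of the median screen respond to that local density, not to
#' degree alone) and each hub is additionally wired to `hubDegreeBoost`
#' random non-hub non-neighbours. The planted hub ids are returned for
#' recovery tests of the median screen.
#'
#' @param cfg a [SynthConfig-class].
#' @param nodes optional [GeneSet-class] of node ids; defaults to
#'   `ppiNodes` synthetic protein ids.
#' @return list with `graph` (undirected simple igraph) and `hubs`
#'   (character vector of planted hub ids).
#' @export
genPpi <- function(cfg, nodes = NULL) {
  stopifnot(is(cfg, "SynthConfig"))
  nm <- if (is.null(nodes)) sprintf("P%03d", seq_len(cfg@ppiNodes))
        else genes(nodes)
  n <- length(nm)
  withSubSeed(cfg@seed, "ppi", {
    g <- igraph::sample_gnp(n, cfg@ppiEdgeProb, directed = FALSE)
    igraph::V(g)$name <- nm
    hubs <- if (cfg@nHubs > 0L) sort(sample(nm, cfg@nHubs)) else character()
    if (length(hubs) >= 2L) {
      pairs <- utils::combn(hubs, 2L)
      pick <- stats::runif(ncol(pairs)) < cfg@hubCliqueProb
      if (any(pick)) g <- igraph::add_edges(g, as.vector(pairs[, pick]))
    }
    for (h in hubs) {
      nbr <- igraph::neighbors(g, h)$name
      pool <- setdiff(nm, c(h, hubs, nbr))
      extra <- sample(pool, min(cfg@hubDegreeBoost, length(pool)))
      if (length(extra)) {
        g <- igraph::add_edges(g, as.vector(rbind(h, extra)))
      }
    }
    list(graph = igraph::simplify(g), hubs = hubs)
  })
}

#' Generate a synthetic docking-energy table
#'
#' One record per ligand-receptor pair with binding free energy uniform in
#' \[-10.5, -4.0\] kcal/mol (the span of typical small-molecule docking
#' scores across the weak/good/strong bands), rounded to 0.1 and graded by
#' [gradeEnergies()].
#'
#' @param cfg a [SynthConfig-class].
#' @param ligands character vector of ligand names.
#' @param receptors character vector of receptor gene symbols.
#' @return graded data.frame of `ligand`, `receptor`, `energy`, `grade`.
#' @export
genDockingMatrix <- function(cfg, ligands, receptors) {
  stopifnot(is(cfg, "SynthConfig"), length(ligands) > 0, length(receptors) > 0)
  grid <- expand.grid(ligand = ligands, receptor = receptors,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withSubSeed(cfg@seed, "docking", {
    grid$energy <- round(stats::runif(nrow(grid), -10.5, -4.0), 1)
    gradeEnergies(grid)
  })
}
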