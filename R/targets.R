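#' Merge disease-gene sources into one target set
#'
#' @param sources list of [GeneSet-class] objects (one per database/source).
#' @param name label for the merged set.
#' @return a [GeneSet-class] holding the union.
#' @export
unionSources <- function(sources, name = "union") {
  stopifnot(is.list(sources), all(vapply(sources, is, logical(1), "GeneSet")))
  GeneSet(unlist(lapply(sources, genes), use.names = FALSE), name = name)
}

#' Venn-region counts over 2-5 gene sources
#'
#' Tallies every non-empty membership pattern across the sources (the
#' `2^k - 1` regions of a k-set Venn diagram). Region labels join the
#' source names with `"∩"`; single-source regions are labelled
#' `"<name> only"`. Labels follow the input order, and counts always sum to
#' the size of the union.
#'
#' @param sources list of 2-5 [GeneSet-class] objects; names taken from
#'   `setName()` (or `S1`, `S2`, ... when unnamed).
#' @return named integer vector of region counts.
#' @examples
#' vennRegions(list(GeneSet(c("A", "B"), "X"), GeneSet(c("B", "C"), "Y")))
#' @export
vennRegions <- function(sources) {
  k <- length(sources)
  if (k < 2L || k > 5L) stopf("vennRegions() needs between 2 and 5 sources, got %d", k)
  stopifnot(all(vapply(sources, is, logical(1), "GeneSet")))
  nms <- vapply(sources, setName, character(1))
  nms[!nzchar(nms)] <- paste0("S", seq_len(k))[!nzchar(nms)]
  all_genes <- unique(unlist(lapply(sources, genes), use.names = FALSE))
  membership <- vapply(sources, function(s) all_genes %in% genes(s),
                       logical(length(all_genes)))
  membership <- matrix(membership, ncol = k)
  counts <- integer(2^k - 1L)
  labels <- character(2^k - 1L)
  for (code in seq_len(2^k - 1L)) {
    inset <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)))
    labels[code] <- if (sum(inset) == 1L) {
      paste(nms[inset], "only")
    } else {
      paste(nms[inset], collapse = "∩")
    }
    counts[code] <- sum(apply(membership, 1L, function(row) all(row == inset)))
  }
  stats::setNames(counts, labels)
}

#' Intersect drug targets with a disease target set
#'
#' Restricts each compound's target set to the disease genes and returns
#' both the global drug-disease intersection (the union of the per-compound
#' restrictions) and the per-compound restricted sets, which later feed the
#' bipartite compound-target network.
#'
#' @param drugTargets named list of [GeneSet-class] target sets, one per
#'   compound (see [readTargetMap()]).
#' @param disease a [GeneSet-class] of disease-associated genes.
#' @return list with elements `intersection` (a [GeneSet-class]) and
#'   `perCompound` (named list of restricted [GeneSet-class]s, empty sets
#'   retained).
#' @export
intersectDrugDisease <- function(drugTargets, disease) {
  stopifnot(is.list(drugTargets),
            all(vapply(drugTargets, is, logical(1), "GeneSet")),
            is(disease, "GeneSet"))
  dset <- genes(disease)
  per <- lapply(drugTargets, function(s) {
    GeneSet(intersect(genes(s), dset), name = setName(s))
  })
  global <- GeneSet(unlist(lapply(per, genes), use.names = FALSE),
                    name = "drug∩disease")
  list(intersection = global, perCompound = per)
}
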