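DOCKING_GRADES <- c("weak", "good", "strong")

#' Grade docking binding energies
#'
#' Classifies ligand-receptor binding free energies (kcal/mol, negative =
#' favourable) into affinity bands: `strong` at energy <= -7.0, `good` at
#' -7.0 < energy <= -5.0, `weak` otherwise. Both boundaries are inclusive
#' on the favourable side; the bands are reported as mutually exclusive.
#' Grading is a pure function of the energy, so re-grading is a no-op.
#'
#' @param records data.frame with columns `ligand`, `receptor`, `energy`;
#'   an existing `grade` column is recomputed.
#' @param goodMax upper bound of the `good` band (default -5.0 kcal/mol).
#' @param strongMax upper bound of the `strong` band (default -7.0 kcal/mol).
#' @param verbose log per-grade counts to `message()`.
#' @return the input with a `grade` factor column
#'   (levels `weak < good < strong`).
#' @examples
#' gradeEnergies(data.frame(ligand = "Luteolin", receptor = "MAPK8",
#'                          energy = -9.9))$grade
#' @export
gradeEnergies <- function(records, goodMax = -5.0, strongMax = -7.0,
                          verbose = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("ligand", "receptor", "energy") %in% names(records)),
            is.numeric(records$energy), strongMax <= goodMax)
  grade <- ifelse(records$energy <= strongMax, "strong",
                  ifelse(records$energy <= goodMax, "good", "weak"))
  records$grade <- factor(grade, levels = DOCKING_GRADES, ordered = TRUE)
  if (verbose) {
    cnt <- table(records$grade)
    message(sprintf("docking grades: %s",
                    paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", ")))
  }
  records
}

#' Rank docking pairs by binding energy
#'
#' Ascending by energy (most favourable first); ties broken by
#' `(ligand, receptor)` lexicographic order for a deterministic report.
#'
#' @param records data.frame with `ligand`, `receptor`, `energy` columns.
#' @param topN number of pairs to keep (default 10).
#' @return the `min(topN, nrow)` best rows, re-rownamed 1..k.
#' @export
rankPairs <- function(records, topN = 10L) {
  stopifnot(is.data.frame(records), topN >= 0)
  out <- records[order(records$energy, records$ligand, records$receptor), ,
                 drop = FALSE]
  out <- utils::head(out, topN)
  rownames(out) <- NULL
  out
}

#' Ligand x receptor binding-energy matrix
#'
#' Dense matrix of energies for heatmap export; pairs absent from the
#' input are `NA`. Row/column order follows first appearance in the input.
#'
#' @param records data.frame with `ligand`, `receptor`, `energy` columns.
#' @return numeric matrix, rows = ligands, columns = receptors.
#' @export
energyMatrix <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("ligand", "receptor", "energy") %in% names(records)))
  lig <- unique(records$ligand)
  rec <- unique(records$receptor)
  m <- matrix(NA_real_, length(lig), length(rec), dimnames = list(lig, rec))
  m[cbind(match(records$ligand, lig), match(records$receptor, rec))] <-
    records$energy
  m
}
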