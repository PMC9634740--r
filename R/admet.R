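#' ADMET eligibility screen on compound tables
#'
#' Retains compounds with oral bioavailability `ob >= obMin` AND
#' drug-likeness `dl >= dlMin`, the standard TCMSP eligibility filter for
#' orally active, drug-like herbal constituents. Both boundaries are
#' inclusive. Input row order is preserved; the screen is idempotent and
#' monotone in both thresholds.
#'
#' @param compounds data.frame as returned by [readCompoundTable()]
#'   (columns `molId`, `name`, `ob`, `dl`).
#' @param obMin minimum oral bioavailability, percent (default 30).
#' @param dlMin minimum drug-likeness (default 0.18).
#' @param verbose log the retained count to `message()`.
#' @return the filtered data.frame.
#' @examples
#' tbl <- readCompoundTable(system.file("extdata", "aa_compounds.tsv",
#'                                      package = "netpharm"))
#' nrow(screenCompounds(tbl))
#' @export
screenCompounds <- function(compounds, obMin = OB_MIN_DEFAULT,
                            dlMin = DL_MIN_DEFAULT, verbose = FALSE) {
  stopifnot(is.data.frame(compounds),
            all(c("molId", "ob", "dl") %in% names(compounds)),
            is.finite(obMin), is.finite(dlMin))
  keep <- compounds$ob >= obMin & compounds$dl >= dlMin
  out <- compounds[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (verbose) {
    message(sprintf("ADMET screen (OB >= %g, DL >= %g): kept %d of %d compounds",
                    obMin, dlMin, nrow(out), nrow(compounds)))
  }
  out
}
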