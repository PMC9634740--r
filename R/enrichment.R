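#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability that a
#' uniform draw of `n` genes from a universe of `N`, of which `K` carry the
#' annotation, contains at least `k` annotated genes. This is the ORA
#' enrichment p-value for an observed overlap of `k`. Terms are accumulated
#' in log space (`lchoose` + log-sum-exp), so the tail is stable far into
#' the extreme range.
#'
#' @param k observed overlap (integer, `0 <= k <= min(n, K)`).
#' @param n query-set size.
#' @param K annotated-set size.
#' @param N universe size (`n, K <= N`).
#' @return the tail probability in \[0, 1\].
#' @examples
#' hypergeomTail(3, 5, 5, 20)   # 1126/15504
#' @export
hypergeomTail <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L, length(N) == 1L)
  k <- as.numeric(k); n <- as.numeric(n); K <- as.numeric(K); N <- as.numeric(N)
  if (any(c(k, n, K, N) < 0) || n > N || K > N) {
    stopf("impossible hypergeometric parameters: k=%g n=%g K=%g N=%g", k, n, K, N)
  }
  if (k > min(n, K)) {
    stopf("overlap k=%g exceeds min(n, K) = %g", k, min(n, K))
  }
  if (k <= max(0, n + K - N)) return(1)
  j <- seq(k, min(n, K))
  logterms <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(logterms)
  p <- exp(m + log(sum(exp(logterms - m))))
  min(p, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`
#' over the `m` input p-values, returned in input order. Invariant to input
#' permutation (up to the same permutation).
#'
#' @param pvals numeric vector of p-values.
#' @return numeric vector of BH-adjusted values, capped at 1.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(pvals) {
  m <- length(pvals)
  if (m == 0L) return(numeric())
  stopifnot(all(pvals >= 0 & pvals <= 1))
  o <- order(pvals)
  q <- pvals[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))       # enforce monotonicity from the largest rank down
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Over-representation analysis of a query gene set
#'
#' Tests each annotation term for enrichment in the query by the upper-tail
#' hypergeometric test, then adjusts across all tested terms by
#' Benjamini-Hochberg. A term is tested when its universe-restricted overlap
#' with the query is at least 1 (zero-overlap terms contribute nothing and
#' are excluded from the adjustment, mirroring common ORA practice). Query
#' genes outside the universe are dropped with a warning. Rows are sorted by
#' p ascending, ties broken by term name.
#'
#' @param query a [GeneSet-class] (or character vector) of genes of interest.
#' @param terms named list of [GeneSet-class] annotation terms (see
#'   [readGmt()]); an optional `categories` vector (same length) labels each
#'   term, e.g. BP/CC/MF/KEGG.
#' @param universe background [GeneSet-class]; default: all genes appearing
#'   in at least one term.
#' @param qMax significance threshold on the adjusted value (default 0.05).
#' @param categories optional character vector of per-term category labels.
#' @return data.frame with columns `term`, `category`, `k` (overlap), `n`
#'   (query size in universe), `K` (term size in universe), `N` (universe
#'   size), `geneRatio` (`k/n`), `p`, `q`, `significant`, `genes`
#'   (overlapping symbols, `/`-separated).
#' @examples
#' uni <- GeneSet(sprintf("G%03d", 1:100), "universe")
#' trm <- list(hit = GeneSet(sprintf("G%03d", 1:10), "hit"),
#'             null = GeneSet(sprintf("G%03d", 51:70), "null"))
#' qry <- GeneSet(sprintf("G%03d", 1:8), "query")
#' runOra(qry, trm, universe = uni)
#' @export
runOra <- function(query, terms, universe = NULL, qMax = 0.05,
                   categories = NULL) {
  if (!is(query, "GeneSet")) query <- GeneSet(query, name = "query")
  stopifnot(is.list(terms), all(vapply(terms, is, logical(1), "GeneSet")))
  if (is.null(categories)) {
    categories <- rep(NA_character_, length(terms))
  }
  stopifnot(length(categories) == length(terms))
  if (is.null(universe)) {
    universe <- GeneSet(unlist(lapply(terms, genes), use.names = FALSE),
                        name = "annotation-universe")
  }
  uni <- genes(universe)
  if (length(uni) == 0L) stopf("empty universe: nothing to test against")
  q_in <- intersect(genes(query), uni)
  dropped <- length(query) - length(q_in)
  if (dropped > 0L) {
    warnf("dropped %d query gene(s) outside the universe", dropped)
  }
  n <- length(q_in); N <- length(uni)
  term_names <- names(terms)
  if (is.null(term_names)) term_names <- vapply(terms, setName, character(1))
  rows <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    tg <- intersect(genes(terms[[i]]), uni)
    ov <- intersect(q_in, tg)
    k <- length(ov)
    if (k == 0L) next
    rows[[i]] <- data.frame(
      term = term_names[i], category = categories[i],
      k = k, n = n, K = length(tg), N = N,
      geneRatio = k / n,
      p = hypergeomTail(k, n, length(tg), N),
      genes = paste(sort(ov), collapse = "/"),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term = character(), category = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), geneRatio = numeric(), p = numeric(),
                      q = numeric(), significant = logical(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out$significant <- out$q <= qMax
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("term", "category", "k", "n", "K", "N", "geneRatio", "p", "q",
          "significant", "genes")]
}

#' Top-N enrichment report per category
#'
#' Selects, within each annotation category, the N significant rows with the
#' lowest p (ties broken by term name), e.g. top 10 per GO ontology and top
#' 30 KEGG pathways for a dot plot whose x axis is the gene ratio `k/n`.
#'
#' @param rows data.frame from [runOra()].
#' @param perCategory named integer vector, e.g.
#'   `c(BP = 10, CC = 10, MF = 10, KEGG = 30)`; unnamed scalar = one global
#'   top-N ignoring categories.
#' @return subset of `rows`, category blocks in `perCategory` order.
#' @export
topNReport <- function(rows, perCategory = c(BP = 10, CC = 10, MF = 10, KEGG = 30)) {
  stopifnot(is.data.frame(rows))
  sig <- rows[rows$significant, , drop = FALSE]
  sig <- sig[order(sig$p, sig$term), , drop = FALSE]
  if (is.null(names(perCategory))) {
    stopifnot(length(perCategory) == 1L)
    out <- utils::head(sig, perCategory)
  } else {
    blocks <- lapply(names(perCategory), function(cat) {
      utils::head(sig[!is.na(sig$category) & sig$category == cat, , drop = FALSE],
                  perCategory[[cat]])
    })
    out <- do.call(rbind, blocks)
  }
  rownames(out) <- NULL
  out
}
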