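test_that("hypergeomTail matches hand-enumerated and boundary cases", {
  # 1126 of the C(20,5) = 15504 draws contain >= 3 of the 5 marked genes
  expect_equal(hypergeomTail(3, 5, 5, 20), 1126 / 15504, tolerance = 1e-12)
  expect_equal(hypergeomTail(0, 5, 5, 20), 1)
  expect_equal(hypergeomTail(6, 6, 6, 6), 1)   # forced draw
  expect_error(hypergeomTail(6, 5, 5, 20), "exceeds")
  expect_error(hypergeomTail(1, 5, 5, 4), "impossible")
})

test_that("hypergeomTail agrees with stats::phyper in the extreme tail", {
  # independent route through the distribution function, log-stable
  cases <- list(c(40, 50, 60, 5000), c(10, 117, 60, 5000), c(3, 5, 5, 20))
  for (cs in cases) {
    expect_equal(hypergeomTail(cs[1], cs[2], cs[3], cs[4]),
                 stats::phyper(cs[1] - 1, cs[3], cs[4] - cs[3], cs[2],
                               lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("bhAdjust matches hand computation and p.adjust", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(5)
  for (rep in 1:10) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), stats::p.adjust(p, method = "BH"))
  }
})

test_that("bhAdjust is permutation-equivariant", {
  set.seed(6)
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
})

test_that("runOra flags all planted terms significant at the fixed seed", {
  cfg <- synthConfig(seed = 11)
  signal <- GeneSet(genes(universeGenes(cfg))[1:117], "signal")
  ann <- genAnnotation(cfg, signal)
  ora <- runOra(signal, ann$terms, universe = universeGenes(cfg))
  expect_true(all(ann$planted %in% ora$term[ora$significant]))
  # planted terms rank at the top by p
  expect_setequal(utils::head(ora$term, length(ann$planted)), ann$planted)
})

test_that("runOra handles degenerate queries and maximal overlap", {
  uni <- GeneSet(sprintf("G%02d", 1:50), "uni")
  trm <- list(a = GeneSet(sprintf("G%02d", 1:10), "a"),
              b = GeneSet(sprintf("G%02d", 21:30), "b"))
  # disjoint query: nothing tested
  out <- runOra(GeneSet(sprintf("G%02d", 41:45), "q"),
                list(a = GeneSet(sprintf("G%02d", 1:10), "a")),
                universe = uni)
  expect_equal(nrow(out), 0L)
  # a term equal to the query has the minimum possible p
  qry <- GeneSet(sprintf("G%02d", 1:10), "q")
  trm$a <- GeneSet(sprintf("G%02d", 1:15), "a")   # strict superset of the query
  out <- runOra(qry, c(trm, list(self = qry)), universe = uni)
  expect_equal(out$term[1L], "self")
  expect_equal(out$p[1L], min(out$p))
  expect_error(runOra(qry, trm, universe = GeneSet()), "empty universe")
  expect_warning(
    runOra(GeneSet(c("G01", "NOTINUNI"), "q"), trm, universe = uni),
    "outside the universe")
})

test_that("zero-overlap terms do not perturb other terms' p-values", {
  uni <- GeneSet(sprintf("G%02d", 1:50), "uni")
  qry <- GeneSet(sprintf("G%02d", 1:8), "q")
  trm <- list(a = GeneSet(sprintf("G%02d", 1:12), "a"),
              b = GeneSet(sprintf("G%02d", 5:20), "b"))
  extra <- list(z = GeneSet(sprintf("G%02d", 40:50), "z"))  # no overlap
  o1 <- runOra(qry, trm, universe = uni)
  o2 <- runOra(qry, c(trm, extra), universe = uni)
  expect_equal(o2[o2$term %in% c("a", "b"), "p"], o1$p)
  expect_equal(nrow(o2), 2L)  # z not tested, not counted in m
  expect_equal(o2$q, o1$q)
})

test_that("topNReport selects lowest-p significant rows per category", {
  rows <- data.frame(
    term = sprintf("t%02d", 1:8),
    category = rep(c("BP", "KEGG"), each = 4),
    k = 3, n = 10, K = 10, N = 100, geneRatio = 0.3,
    p = c(0.001, 0.002, 0.003, 0.2, 0.004, 0.001, 0.002, 0.9),
    q = c(0.01, 0.01, 0.01, 0.4, 0.02, 0.01, 0.01, 0.95),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    genes = "A/B/C", stringsAsFactors = FALSE)
  rep2 <- topNReport(rows, c(BP = 2, KEGG = 2))
  expect_equal(rep2$term, c("t01", "t02", "t06", "t07"))
  # global top-N ignores categories
  expect_equal(nrow(topNReport(rows, 3)), 3L)
})
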