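test_that("generators are byte-identical under a fixed config", {
  cfg <- synthConfig(seed = 13, nCompounds = 100L)
  expect_identical(genCompounds(cfg), genCompounds(cfg))
  s1 <- genDiseaseSources(cfg); s2 <- genDiseaseSources(cfg)
  expect_identical(lapply(s1, genes), lapply(s2, genes))
  p1 <- genPpi(cfg); p2 <- genPpi(cfg)
  expect_identical(igraph::as_edgelist(p1$graph), igraph::as_edgelist(p2$graph))
  expect_identical(p1$hubs, p2$hubs)
  a1 <- genAnnotation(cfg, s1[[1]]); a2 <- genAnnotation(cfg, s2[[1]])
  expect_identical(lapply(a1$terms, genes), lapply(a2$terms, genes))
  # different seeds give different draws
  expect_false(identical(genCompounds(cfg),
                         genCompounds(synthConfig(seed = 14, nCompounds = 100L))))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(genCompounds(synthConfig(seed = 1, nCompounds = 10L)))
  expect_identical(.Random.seed, before)
})

test_that("compound generator hits the target ADMET pass fraction", {
  cfg <- synthConfig(seed = 1, nCompounds = 2000L, fracPass = 0.5)
  tbl <- genCompounds(cfg)
  frac <- nrow(screenCompounds(tbl)) / nrow(tbl)
  expect_lt(abs(frac - 0.5), 0.05)
  expect_true(all(tbl$ob >= 0))
  expect_true(all(tbl$dl >= 0 & tbl$dl <= 1))
  expect_equal(nrow(genCompounds(synthConfig(nCompounds = 0L))), 0L)
})

test_that("disease sources realise the configured sizes and overlap", {
  cfg <- synthConfig(seed = 21, sourceSizes = rep(400L, 4), pairwiseOverlap = 0.2)
  src <- genDiseaseSources(cfg)
  expect_length(src, 4L)
  expect_equal(unname(vapply(src, length, integer(1))), rep(400L, 4))
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(abs(jac(genes(src[[i]]), genes(src[[j]])) - 0.2), 0.05)
  }
})

test_that("drug targets overlap the disease union by construction", {
  cfg <- synthConfig(seed = 22, nCompounds = 30L)
  cmp <- genCompounds(cfg)
  dis <- unionSources(genDiseaseSources(cfg))
  tg <- genDrugTargets(cfg, cmp, dis)
  expect_named(tg, cmp$molId)
  sizes <- vapply(tg, length, integer(1))
  expect_true(all(sizes >= cfg@targetsPerCompound[1] &
                  sizes <= cfg@targetsPerCompound[2]))
  inter <- intersectDrugDisease(tg, dis)
  expect_gt(length(inter$intersection), 0L)
})

test_that("planted hubs out-degree the median at the example scale", {
  cfg <- synthConfig(seed = 7, ppiNodes = 117L, nHubs = 11L,
                     hubDegreeBoost = 20L)
  ppi <- genPpi(cfg)
  deg <- degreeCentrality(ppi$graph)
  expect_true(all(deg[ppi$hubs] > median(deg)))
  # no hubs requested -> empty hub set
  p0 <- genPpi(synthConfig(seed = 7, nHubs = 0L))
  expect_length(p0$hubs, 0L)
})

test_that("docking generator grades every pair and spans the energy range", {
  cfg <- synthConfig(seed = 9)
  d <- genDockingMatrix(cfg, ligands = c("L1", "L2"), receptors = c("R1", "R2", "R3"))
  expect_equal(nrow(d), 6L)
  expect_true(all(d$energy >= -10.5 & d$energy <= -4.0))
  expect_equal(d, gradeEnergies(d))
})
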