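test_that("unionSources merges and normalizes", {
  s <- list(GeneSet(c("A", "B"), "X"), GeneSet(c("b", "C"), "Y"))
  expect_setequal(genes(unionSources(s)), c("A", "B", "C"))
  expect_equal(genes(unionSources(s[1])), genes(s[[1]]))
})

test_that("vennRegions matches the hand-worked two-set case", {
  vr <- vennRegions(list(GeneSet(c("A", "B"), "S1"), GeneSet(c("B", "C"), "S2")))
  expect_equal(vr[["S1 only"]], 1L)
  expect_equal(vr[["S2 only"]], 1L)
  expect_equal(vr[["S1∩S2"]], 1L)
  vr0 <- vennRegions(list(GeneSet(c("A"), "S1"), GeneSet(c("B"), "S2")))
  expect_equal(vr0[["S1∩S2"]], 0L)
})

test_that("vennRegions equals an exhaustive per-gene membership tally", {
  set.seed(31)
  pool <- sprintf("G%03d", 1:60)
  for (k in 2:5) {
    sources <- lapply(seq_len(k), function(i) {
      GeneSet(sample(pool, sample(5:40, 1)), name = sprintf("S%d", i))
    })
    vr <- vennRegions(sources)
    expect_length(vr, 2^k - 1L)
    # oracle: tally each gene's membership pattern directly
    uni <- unique(unlist(lapply(sources, genes)))
    pat <- vapply(uni, function(g) {
      paste(vapply(sources, function(s) g %in% genes(s), logical(1)),
            collapse = "")
    }, character(1))
    expect_equal(sum(vr), length(uni))
    # spot-check every region against the tally
    for (code in seq_len(2^k - 1L)) {
      inset <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)))
      expect_equal(unname(vr[code]),
                   sum(pat == paste(inset, collapse = "")))
    }
  }
})

test_that("union size equals brute-force union of generated source files", {
  cfg <- synthConfig(seed = 3)
  sources <- genDiseaseSources(cfg)
  u <- unionSources(sources)
  expect_equal(length(u),
               length(unique(unlist(lapply(sources, genes)))))
  expect_equal(sum(vennRegions(sources)), length(u))
})

test_that("drug-disease intersection returns global and per-compound sets", {
  m <- list(c1 = GeneSet(c("X", "Y"), "c1"))
  out <- intersectDrugDisease(m, GeneSet(c("Y", "Z"), "dis"))
  expect_equal(genes(out$intersection), "Y")
  expect_equal(genes(out$perCompound$c1), "Y")

  out0 <- intersectDrugDisease(m, GeneSet("Q", "dis"))
  expect_equal(length(out0$intersection), 0L)
  expect_equal(length(out0$perCompound$c1), 0L)
})

test_that("global intersection equals the union of per-compound intersections", {
  set.seed(11)
  pool <- sprintf("G%03d", 1:80)
  for (rep in 1:5) {
    m <- lapply(1:6, function(i) GeneSet(sample(pool, 15), sprintf("c%d", i)))
    names(m) <- sprintf("c%d", 1:6)
    dis <- GeneSet(sample(pool, 30), "dis")
    out <- intersectDrugDisease(m, dis)
    expect_setequal(genes(out$intersection),
                    unique(unlist(lapply(out$perCompound, genes))))
  }
})
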