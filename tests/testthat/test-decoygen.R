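test_that("d0 follows the closed form and is floored", {
  expect_equal(tmD0(165), 1.24 * 150^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(round(tmD0(165), 3), 4.788)
  expect_equal(tmD0(16), 0.5)  # floor engages for tiny chains
})

test_that("TM-score: self-identity, rigid invariance, fold discrimination", {
  h <- fixLibrary()$p1
  expect_equal(tmScore(h, h), 1, tolerance = 1e-6)
  # rigid transform of either argument changes nothing
  hT <- ProteinStructure({
    a <- atomData(h)
    a[, c("x", "y", "z")] <- rigidTransform(a[, c("x", "y", "z")], 7L)
    a
  }, "p1T")
  expect_equal(tmScore(hT, h), 1, tolerance = 1e-4)
  expect_equal(tmScore(h, hT), 1, tolerance = 1e-4)
  # helix vs strand-only fold scores below the 0.5 fold threshold
  e <- fixLibrary()$p2
  expect_lt(tmScore(h, e), 0.5)
  expect_lt(tmScore(e, h), 0.5)
  expect_error(tmScore(caCoords(h)[1:10, ], h), class = "ppiLengthError")
})

test_that("TM normalization is by the reference length", {
  long <- makeChain(40, "H", seed = 211L, id = "long")
  short <- ProteinStructure(atomData(long)[1:(20 * 5), ], "short")
  # identical coordinates over the overlap: score differs by normalization
  expect_equal(tmScore(short, short), 1, tolerance = 1e-6)
  tmLongRef <- tmScore(short, long)   # 20 aligned of 40 reference
  tmShortRef <- tmScore(long, short)  # full cover of 20 reference
  expect_lt(tmLongRef, 0.6)
  expect_gt(tmShortRef, 0.9)
})

test_that("nearest-analog search honors exclusions and the tie-break", {
  lib <- fixLibrary()
  idx <- fixPairingIndex()
  tmTab <- PPIscreen:::.tmTable(lib)
  a <- nearestAnalog("p1", lib, idx, tmTab)
  # brute-force: best TM among candidates excluding self and partner p2
  cand <- setdiff(names(lib), c("p1", "p2"))
  expect_equal(a$analogId, cand[which.max(tmTab[cand, "p1"])])
  expect_identical(a$rankUsed, "best")
  # ties within 1e-6 go to the lexicographically lower id
  tt <- tmTab
  tt[c("p3", "p5"), "p1"] <- 0.9
  tt["p4", "p1"] <- 0.1; tt["p6", "p1"] <- 0.1
  expect_identical(nearestAnalog("p1", lib, idx, tt)$analogId, "p3")
  expect_error(nearestAnalog("zz", lib, idx, tmTab),
               class = "ppiAnalogError")
})

test_that("decoy pairings never reconstitute an active pairing", {
  lib <- fixLibrary()
  idx <- fixPairingIndex()
  tmTab <- PPIscreen:::.tmTable(lib)
  active <- function(x, y)
    any((idx$id1 == x & idx$id2 == y) | (idx$id1 == y & idx$id2 == x))
  for (cid in idx$complex_id) {
    pick <- decoyPairing(cid, lib, idx, tmTab)
    expect_false(active(pick$analog1$analogId, pick$analog2$analogId))
  }
  # force the best/best combination to be an active pairing: the
  # second-best rule must engage for exactly one slot
  tt <- tmTab
  tt[, ] <- 0.2
  tt["p3", "p1"] <- 0.9  # best analog of p1 -> p3
  tt["p4", "p2"] <- 0.9  # best analog of p2 -> p4; p3-p4 is active (cxB)
  tt["p5", "p1"] <- 0.8  # second-best of p1
  tt["p6", "p2"] <- 0.7  # second-best of p2
  pick <- decoyPairing("cxA", lib, idx, tt)
  expect_false(active(pick$analog1$analogId, pick$analog2$analogId))
  ranks <- c(pick$analog1$rankUsed, pick$analog2$rankUsed)
  expect_equal(sum(ranks == "second_best"), 1L)
})

test_that("decoy building recovers exact placement for identical analogs", {
  lib <- fixLibrary()
  template <- makeTemplateComplex(lib$p1, lib$p2, "cxA")
  built <- buildDecoy(template, lib$p1, lib$p2)
  expect_equal(as.matrix(atomData(built$decoy)[, c("x", "y", "z")]),
               as.matrix(atomData(template)[, c("x", "y", "z")]),
               tolerance = 1e-9)
  expect_equal(built$recipe@transforms[[1]]@rmsd, 0, tolerance = 1e-9)
  expect_identical(names(built$sequences), c("p1", "p2"))
  # rigidly moved analog: transform recovered exactly
  moved <- ProteinStructure({
    a <- atomData(lib$p1)
    a[, c("x", "y", "z")] <- rigidTransform(a[, c("x", "y", "z")], 8L)
    a
  }, "p1m")
  built2 <- buildDecoy(template, moved, lib$p2)
  expect_equal(built2$recipe@transforms[[1]]@rmsd, 0, tolerance = 1e-6)
  e1 <- residueData(built2$decoy)$entity == 1L
  sel <- atomData(built2$decoy)$resIdx %in% which(e1)
  expect_equal(as.matrix(atomData(built2$decoy)[sel, c("x", "y", "z")]),
               as.matrix(atomData(template)[sel, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("size-bias report summarizes analog/template length ratios", {
  lib <- fixLibrary()
  idx <- fixPairingIndex()
  template <- makeTemplateComplex(lib$p1, lib$p2, "cxA")
  b <- buildDecoy(template, lib$p3, lib$p4,
                  list(analog1 = list(analogId = "p3", tm = 0.9,
                                      rankUsed = "best"),
                       analog2 = list(analogId = "p4", tm = 0.9,
                                      rankUsed = "best")))
  rep1 <- sizeBiasReport(list(b$recipe), lib, idx)
  expect_equal(rep1$mean_ratio, 1)  # same lengths
  expect_equal(rep1$frac_larger, 0)
  # longer analogs push the ratio above 1
  libL <- lib
  libL$p3 <- makeChain(30, "H", seed = 221L, id = "p3")
  rep2 <- sizeBiasReport(list(b$recipe), libL, idx)
  expect_gt(rep2$mean_ratio, 1)
  expect_error(sizeBiasReport(list(), lib, idx), class = "ppiDataError")
})
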