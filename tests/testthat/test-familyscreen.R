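test_that("pairing enumeration is the full product in row-major order", {
  p <- enumeratePairings(paste0("L", 1:18), paste0("R", 1:28))
  expect_equal(nrow(p), 504L)
  small <- enumeratePairings(c("a", "b"), c("x", "y", "z"))
  expect_equal(small$ligand, rep(c("a", "b"), each = 3))
  expect_equal(small$receptor, rep(c("x", "y", "z"), 2))
  expect_equal(nrow(enumeratePairings("a", "x")), 1L)
  expect_error(enumeratePairings(c("a", "a"), "x"), class = "ppiIdError")
  expect_error(enumeratePairings(character(0), "x"), class = "ppiIdError")
})

test_that("top-k hits rank receptors with deterministic tie-breaks", {
  s <- matrix(c(0.9, 0.5, 0.1,
                0.4, 0.8, 0.3,
                0.2, 0.7, 0.6), 3, byrow = TRUE,
              dimnames = list(paste0("L", 1:3), paste0("R", 1:3)))
  mask <- matrix(FALSE, 3, 3, dimnames = dimnames(s))
  mask["L1", "R1"] <- TRUE   # known receptor scores highest -> hit at k=1
  mask["L2", "R3"] <- TRUE   # ranked 3rd -> only hit at k=3
  mask["L3", "R3"] <- TRUE   # ranked 2nd -> hit at k=2
  g <- SelectivityGrid(s, mask)
  h1 <- topkHits(g, 1L)
  expect_equal(h1$n_hits, 1L)
  expect_true(h1$hits$hit[h1$hits$ligand == "L1"])
  h2 <- topkHits(g, 2L)
  expect_equal(h2$n_hits, 2L)
  h3 <- topkHits(g, 3L)
  expect_equal(h3$n_hits, 3L)
  # monotone in k
  expect_true(all(h1$hits$hit <= h2$hits$hit))
  expect_true(all(h2$hits$hit <= h3$hits$hit))
  # ligand with no known receptor is excluded with a warning
  mask["L2", ] <- FALSE
  expect_warning(hx <- topkHits(SelectivityGrid(s, mask), 1L),
                 "no known receptor")
  expect_equal(hx$n_ligands, 2L)
  # score tie: lexicographically lower receptor id wins the rank
  sT <- s; sT["L1", ] <- 0.5
  maskT <- mask; maskT["L1", ] <- FALSE; maskT["L1", "R1"] <- TRUE
  expect_true(suppressWarnings(
    topkHits(SelectivityGrid(sT, maskT), 1L))$hits$hit[1])
})

test_that("grid ROC delegates to the rank AUC on flattened cells", {
  s <- matrix(runif(12), 3, 4,
              dimnames = list(paste0("L", 1:3), paste0("R", 1:4)))
  mask <- matrix(FALSE, 3, 4, dimnames = dimnames(s))
  mask[cbind(1:3, c(1, 2, 3))] <- TRUE
  g <- SelectivityGrid(s, mask)
  r <- gridRoc(g)
  expect_equal(r$auc, rocAuc(as.numeric(s), as.logical(mask)))
  # perfect grid
  sP <- ifelse(mask, 1, 0)
  dimnames(sP) <- dimnames(s)
  expect_equal(gridRoc(SelectivityGrid(sP, mask))$auc, 1)
  # reordering ligands/receptors changes nothing
  g2 <- SelectivityGrid(s[3:1, 4:1], mask[3:1, 4:1])
  expect_equal(gridRoc(g2)$auc, r$auc)
  expect_error(gridRoc(SelectivityGrid(s)), class = "ppiDataError")
})

test_that("an end-to-end screen scores docked pairings above separated ones", {
  tab <- featureTableFromSet(fixScreenSet())
  trained <- trainModel(tab, folds = 3L, seed = 31L)
  # 2x2 grid: L1/R1 docked+confident, everything else separated+uncertain
  ligA <- makeChain(20, "H", seed = 301L, id = "A")
  ligB <- makeChain(20, "E", seed = 302L, id = "A")
  recX <- makeChain(20, "H", seed = 303L, id = "B")
  recY <- makeChain(20, "H", seed = 304L, id = "B")
  mkEntry <- function(lig, rec, ligId, recId, mode, scen, seed) {
    m <- makeComplex(lig, rec, mode, seed = seed,
                     complexId = paste(ligId, recId, sep = "_"))
    list(ligand = ligId, receptor = recId,
         models = list(list(model = m,
                            conf = makeConfidence(m, scen,
                                                  seed = seed + 1L))))
  }
  entries <- list(
    mkEntry(ligA, recX, "L1", "R1", "docked", "confident_interface", 310L),
    mkEntry(ligA, recY, "L1", "R2", "separated", "uncertain_interface", 320L),
    mkEntry(ligB, recX, "L2", "R1", "separated", "uncertain_interface", 330L),
    mkEntry(ligB, recY, "L2", "R2", "separated", "uncertain_interface", 340L))
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, byrow = TRUE,
                 dimnames = list(c("L1", "L2"), c("R1", "R2")))
  g <- screenGrid(entries, trained, knownMask = mask)
  s <- gridScores(g)
  expect_equal(dim(s), c(2L, 2L))
  expect_true(all(is.finite(s)))
  expect_equal(unname(which.max(s["L1", ])), 1L)  # docked cell tops its row
  # determinism
  g2 <- screenGrid(entries, trained, knownMask = mask)
  expect_identical(gridScores(g2), s)
  # a missing pairing is an incomplete-grid error naming the gap
  expect_error(screenGrid(entries[-2], trained,
                          ligands = c("L1", "L2"),
                          receptors = c("R1", "R2")),
               "L1 R2", class = "ppiGridError")
})

test_that("trimeric 3:1 grouping feeds the screen unchanged", {
  copies <- lapply(1:3, function(k)
    makeChain(15, "E", seed = 350L + k, id = LETTERS[k]))
  rec <- makeChain(15, "H", seed = 354L, id = "D")
  m <- makeComplex(copies, rec, "docked", seed = 355L, complexId = "tnf")
  expect_identical(unname(entityOfChain(m)), c(1L, 1L, 1L, 2L))
  conf <- makeConfidence(m, "confident_interface", seed = 356L)
  v <- extractFeatures(m, conf)
  expect_length(v, 57L)
  expect_true(all(is.finite(v)))
})
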