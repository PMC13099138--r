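test_that("representative atom is C-beta, C-alpha for glycine, with fallback", {
  m <- pointModel(matrix(c(1, 2, 3), 1), matrix(c(30, 0, 0), 1),
                  aa1 = "A", aa2 = "G")
  expect_equal(representativeAtom(m, 1L), c(1, 2, 3))
  expect_equal(representativeAtom(m, 2L), c(30, 0, 0))
  # non-glycine with CA only falls back with a warning
  a <- atomData(m)
  a <- a[!(a$chain == "A" & a$elety == "CB"), ]
  a$resIdx <- NULL
  m2 <- ComplexModel(a, entitySpec = c(A = 1L, B = 2L))
  expect_warning(v <- representativeAtom(m2, 1L), "C-alpha")
  expect_equal(v, c(1 + 1.5, 2, 3))
  # backbone-only (no CA) is a geometry error
  a3 <- atomData(m)
  a3$elety[a3$chain == "A"] <- c("N", "O")
  a3$resIdx <- NULL
  m3 <- ComplexModel(a3, entitySpec = c(A = 1L, B = 2L))
  expect_error(representativeAtom(m3, 1L), class = "ppiGeometryError")
})

test_that("interface rule is inclusive at the 12 A boundary", {
  near <- pointModel(matrix(c(0, 0, 0), 1), matrix(c(11.99, 0, 0), 1))
  far <- pointModel(matrix(c(0, 0, 0), 1), matrix(c(12.01, 0, 0), 1))
  exact <- pointModel(matrix(c(0, 0, 0), 1), matrix(c(12, 0, 0), 1))
  expect_equal(nrow(interfacePairs(findInterface(near))), 1L)
  expect_equal(nrow(interfacePairs(findInterface(far))), 0L)
  expect_equal(nrow(interfacePairs(findInterface(exact))), 1L)
})

test_that("interface pairs match a brute-force all-pairs distance check", {
  # 3 residues per entity, all mutually within cutoff
  tri <- matrix(c(0, 0, 0, 4, 0, 0, 0, 4, 0), 3, byrow = TRUE)
  m <- pointModel(tri, tri + 4)
  im <- findInterface(m)
  expect_equal(nrow(interfacePairs(im)), 9L)
  expect_length(interfaceResidues(im, 1L), 3L)
  expect_length(interfaceResidues(im, 2L), 3L)

  # random configuration vs naive double loop over representative atoms
  md <- fixDocked()
  im2 <- findInterface(md)
  rep <- PPIscreen:::.repCoords(md)
  ent <- residueData(md)$entity
  want <- list()
  for (i in which(ent == 1L)) for (j in which(ent == 2L)) {
    if (sqrt(sum((rep[i, ] - rep[j, ])^2)) <= 12)
      want[[length(want) + 1L]] <- c(i, j)
  }
  want <- do.call(rbind, want)
  got <- interfacePairs(im2)
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
               ignore_attr = TRUE)
  # separated chains give an empty map
  expect_equal(nrow(interfacePairs(findInterface(fixSeparated()))), 0L)
})

test_that("interface is invariant to rigid motion and monotone in cutoff", {
  m <- fixDocked()
  im <- findInterface(m)
  imT <- findInterface(transformModel(m, seed = 9L))
  expect_equal(interfacePairs(imT), interfacePairs(im))
  p10 <- interfacePairs(findInterface(m, 10))
  p12 <- interfacePairs(findInterface(m, 12))
  key <- function(p) paste(p[, 1], p[, 2])
  expect_true(all(key(p10) %in% key(p12)))
  # entity swap transposes the map
  sw <- groupEntities(m, setNames(c(2L, 1L), names(entityOfChain(m))))
  imS <- findInterface(sw)
  expect_setequal(key(interfacePairs(imS)),
                  paste(interfacePairs(im)[, 2], interfacePairs(im)[, 1]))
  expect_identical(interfaceResidues(imS, 1L), interfaceResidues(im, 2L))
})

test_that("residue chemistry classes follow the shipped table", {
  expect_identical(classifyResidue("K"), "charged+")
  expect_identical(classifyResidue("D"), "charged-")
  expect_setequal(classifyResidue("F"), c("hydrophobic", "aromatic"))
  expect_identical(classifyResidue("S"), "polar")
  expect_true("polar" %in% classifyResidue("H"))  # His is not charged
  expect_identical(classifyResidue("G"), "special")
  expect_error(classifyResidue("B"), class = "ppiClassificationError")
})

test_that("secondary structure recovers helix, sheet, and coil fixtures", {
  # ideal 20-residue helices: nearly all H
  ssH <- assignSecondaryStructure(fixSeparated())
  expect_gte(sum(ssH[1:20] == "H"), 14L)
  # flat antiparallel sheet: central residues E
  ssE <- assignSecondaryStructure(makeSheetPair(16))
  expect_gte(sum(ssE == "E"), 20L)
  expect_true(all(ssE[c(5:12, 21:28)] == "E"))
  # isolated extended strands with no partner: all coil
  mS <- makeComplex(makeChain(20, "E", seed = 51L),
                    makeChain(20, "E", seed = 52L, id = "B"),
                    "separated", seed = 53L)
  expect_true(all(assignSecondaryStructure(mS) == "C"))
  # all-coil chains carry no H/E runs
  mC <- makeComplex(makeChain(20, "C", seed = 54L),
                    makeChain(20, "C", seed = 55L, id = "B"),
                    "separated", seed = 56L)
  expect_true(all(assignSecondaryStructure(mC) == "C"))
})
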