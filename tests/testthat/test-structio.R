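test_that("PDB and mmCIF parsing agree and enforce the two-chain rule", {
  m <- makeComplex(makeChain(15, "H", seed = 1),
                   makeChain(15, "E", seed = 2, id = "B"),
                   "docked", seed = 3, complexId = "io1")
  pdb <- tempfile(fileext = ".pdb")
  cif <- tempfile(fileext = ".cif")
  writeStructure(m, pdb)
  writeStructureCif(m, cif)
  mp <- readStructure(pdb)
  mc <- readStructure(cif)
  expect_equal(nResidues(mp), 30L)
  inv <- c("chain", "resno", "resid", "elety")
  expect_identical(atomData(mp)[, inv], atomData(mc)[, inv])
  expect_equal(as.matrix(atomData(mp)[, c("x", "y", "z")]),
               as.matrix(atomData(mc)[, c("x", "y", "z")]),
               tolerance = 1e-6)
  # single chain fails the structural precondition
  one <- extractChain(m, "A")
  single <- tempfile(fileext = ".pdb")
  writeStructure(one, single)
  expect_error(readStructure(single), class = "ppiStructuralError")
  expect_error(readStructure(tempfile(fileext = ".pdb")),
               class = "ppiParseError")
})

test_that("write/read round trip preserves inventory and coordinates", {
  m <- fixDocked()
  p <- tempfile(fileext = ".pdb")
  writeStructure(m, p)
  m2 <- readStructure(p)
  expect_equal(nResidues(m2), nResidues(m))
  expect_identical(atomData(m2)$elety, atomData(m)$elety)
  expect_lt(max(abs(as.matrix(atomData(m2)[, c("x", "y", "z")]) -
                    as.matrix(atomData(m)[, c("x", "y", "z")]))), 1e-3)
})

test_that("confidence files parse, validate ranges, and check pairing", {
  n <- 20L
  paeM <- matrix(5, n, n); diag(paeM) <- 0.2
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(plddt = rep(90, n),
                            pae = apply(paeM, 1, as.numeric,
                                        simplify = FALSE),
                            ptm = 0.7, iptm = 0.6),
                       f, auto_unbox = TRUE)
  b <- readConfidence(f, n)
  expect_true(all(pae(b)[upper.tri(pae(b))] == 5))
  expect_equal(iptm(b), 0.6)

  # out-of-range pLDDT is a validation error
  jsonlite::write_json(list(plddt = c(101, rep(90, n - 1)),
                            pae = apply(paeM, 1, as.numeric,
                                        simplify = FALSE)),
                       f, auto_unbox = TRUE)
  expect_error(readConfidence(f, n), class = "ppiValidationError")

  # non-square / mismatched PAE is a pairing error
  jsonlite::write_json(list(plddt = rep(90, n),
                            pae = apply(paeM[-1, ], 1, as.numeric,
                                        simplify = FALSE)),
                       f, auto_unbox = TRUE)
  expect_error(readConfidence(f, n), class = "ppiPairingError")

  # missing required key names the key
  jsonlite::write_json(list(plddt = rep(90, n)), f, auto_unbox = TRUE)
  expect_error(readConfidence(f, n), "pae", class = "ppiDialectError")

  # missing iptm/ptm imputed 0 with a warning
  jsonlite::write_json(list(plddt = rep(90, n),
                            pae = apply(paeM, 1, as.numeric,
                                        simplify = FALSE)),
                       f, auto_unbox = TRUE)
  w <- capture_warnings(b2 <- readConfidence(f, n))
  expect_match(w, "imputed", all = TRUE)
  expect_length(w, 2L)  # ptm and iptm both imputed
  expect_equal(iptm(b2), 0)
})

test_that("common score-file key variants map onto the dialect", {
  n <- 16L
  paeM <- matrix(3, n, n)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(pLDDT = rep(80, n),
                            predicted_aligned_error =
                              apply(paeM, 1, as.numeric, simplify = FALSE),
                            ipTM = 0.5, pTM = 0.6),
                       f, auto_unbox = TRUE)
  b <- readConfidence(f, n)
  expect_equal(iptm(b), 0.5)
  expect_equal(ptm(b), 0.6)
})

test_that("entity grouping generalizes to 3:1 stoichiometry and validates", {
  chains <- lapply(1:4, function(k)
    makeChain(15, "H", seed = 400L + k, id = LETTERS[k]))
  m <- makeComplex(chains[1:3], chains[[4]], "separated", seed = 405L)
  expect_identical(unname(entityOfChain(m)), c(1L, 1L, 1L, 2L))
  # regroup: single ligand copy vs rest
  m2 <- groupEntities(m, c(A = 1L, B = 2L, C = 2L, D = 2L))
  expect_equal(sum(residueData(m2)$entity == 1L), 15L)
  expect_equal(nResidues(m2), nResidues(m))
  # idempotent
  m3 <- groupEntities(m2, c(A = 1L, B = 2L, C = 2L, D = 2L))
  expect_identical(residueData(m3), residueData(m2))
  expect_error(groupEntities(m, c(A = 1L, B = 1L, C = 1L, D = 1L)),
               class = "ppiSpecError")
  expect_error(groupEntities(m, c(A = 1L, B = 2L)),
               class = "ppiSpecError")
})

test_that("FASTA writing wraps at 60 and validates records", {
  f <- tempfile(fileext = ".fasta")
  writeFasta(list(c("d1_A", "ACDE")), f)
  expect_identical(readLines(f), c(">d1_A", "ACDE"))
  writeFasta(c(r1 = strrep("ACDEFGHIKL", 13), r2 = "MNPQ"), f)
  lines <- readLines(f)
  expect_identical(lines[1], ">r1")
  expect_true(all(nchar(lines[2:3]) == c(60, 60)))
  expect_identical(lines[5], ">r2")
  expect_error(writeFasta(c(bad = "AC1DE"), f), class = "ppiRecordError")
  expect_error(writeFasta(c(bad = ""), f), class = "ppiRecordError")
})

test_that("metadata filter routes complexes per the dataset rules", {
  base <- list(resolution = 2.0, pct_identity = 25, total_len = 400,
               min_chain_len = 150, is_homodimer = FALSE,
               is_antibody = FALSE)
  expect_identical(filterComplexMetadata(base), "keep_protein_protein")
  expect_identical(filterComplexMetadata(modifyList(base, list(min_chain_len = 49))),
                   "route_peptide")
  expect_identical(filterComplexMetadata(modifyList(base, list(total_len = 1600))),
                   "drop")
  expect_identical(filterComplexMetadata(modifyList(base, list(resolution = 3.1))),
                   "drop")
  expect_identical(filterComplexMetadata(modifyList(base, list(pct_identity = 31))),
                   "drop")
  expect_identical(filterComplexMetadata(modifyList(base, list(is_homodimer = TRUE))),
                   "drop")
  expect_error(filterComplexMetadata(base[-1]), class = "ppiDataError")
})
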