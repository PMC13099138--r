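# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fixHelixA <- function() fixture("helixA", function()
  makeChain(20, "H", seed = 101L, id = "A"))
fixHelixB <- function() fixture("helixB", function()
  makeChain(20, "H", seed = 102L, id = "B"))

fixDocked <- function() fixture("docked", function()
  makeComplex(fixHelixA(), fixHelixB(), "docked", seed = 103L,
              complexId = "fxd"))
fixClashed <- function() fixture("clashed", function()
  makeComplex(fixHelixA(), fixHelixB(), "clashed", seed = 103L,
              complexId = "fxc"))
fixSeparated <- function() fixture("separated", function()
  makeComplex(fixHelixA(), fixHelixB(), "separated", seed = 103L,
              complexId = "fxs"))

fixConfident <- function() fixture("confident", function()
  makeConfidence(fixDocked(), "confident_interface", seed = 104L))

# Synthetic decoy-generation library: three near-identical pairs of folds
# so each protein has an obvious closest analog, plus an odd one out.
fixLibrary <- function() fixture("library", function() {
  list(p1 = makeChain(24, "H", seed = 201L, id = "p1"),
       p2 = makeChain(24, "E", seed = 202L, id = "p2"),
       p3 = perturbChain(makeChain(24, "H", seed = 201L, id = "p3"), 0.3,
                         301L),
       p4 = perturbChain(makeChain(24, "E", seed = 202L, id = "p4"), 0.3,
                         302L),
       p5 = perturbChain(makeChain(24, "H", seed = 201L, id = "p5"), 0.8,
                         303L),
       p6 = perturbChain(makeChain(24, "E", seed = 202L, id = "p6"), 0.8,
                         304L))
})

fixScreenSet <- function() fixture("screenSet", function()
  makeScreeningSet(6L, 6L, modelsPerComplex = 2L, chainLength = 24L,
                   seed = 501L))

fixPairingIndex <- function() fixture("pairingIndex", function()
  data.frame(complex_id = c("cxA", "cxB", "cxC"),
             id1 = c("p1", "p3", "p5"), id2 = c("p2", "p4", "p6"),
             stringsAsFactors = FALSE))

# Add seeded coordinate noise to a chain (keeps topology, lowers TM).
perturbChain <- function(ps, sd, seed) {
  set.seed(seed)
  a <- ps@atoms
  a[, c("x", "y", "z")] <- as.matrix(a[, c("x", "y", "z")]) +
    matrix(rnorm(nrow(a) * 3, 0, sd), ncol = 3)
  ProteinStructure(a, ps@id)
}

# Random rigid transform applied to an atom table or coordinate matrix.
rigidTransform <- function(xyz, seed = 1L) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  t <- rnorm(3, 0, 20)
  sweep(as.matrix(xyz) %*% R, 2, t, "+")
}

transformModel <- function(model, seed = 1L) {
  a <- atomData(model)
  a[, c("x", "y", "z")] <- rigidTransform(a[, c("x", "y", "z")], seed)
  a$resIdx <- NULL
  ComplexModel(a, complexId = complexId(model),
               modelRank = modelRank(model),
               entitySpec = entityOfChain(model))
}

# Minimal hand-built two-residue-per-chain model for targeted geometry
# tests: residues at controlled representative-atom positions.
pointModel <- function(pos1, pos2, aa1 = NULL, aa2 = NULL) {
  mk <- function(pos, chain, aa) {
    rows <- lapply(seq_len(nrow(pos)), function(i) {
      resid <- if (is.null(aa)) "ALA" else PPIscreen:::.aa123(aa[i])
      at <- data.frame(chain = chain, resno = i, ins = "",
                       resid = resid, elety = c("CA", "CB"),
                       element = "C",
                       x = pos[i, 1], y = pos[i, 2], z = pos[i, 3],
                       b = 0, stringsAsFactors = FALSE)
      if (resid == "GLY") {
        at <- at[1, , drop = FALSE]  # representative = CA at `pos`
      } else {
        at$x[1] <- at$x[1] + 1.5     # CB (the representative) stays at `pos`
      }
      at
    })
    do.call(rbind, rows)
  }
  ComplexModel(rbind(mk(pos1, "A", aa1), mk(pos2, "B", aa2)),
               entitySpec = c(A = 1L, B = 2L))
}
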