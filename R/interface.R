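# Interface detection, residue chemistry classes, secondary structure.

#' Representative atom of a residue
#'
#' C-beta coordinate; C-alpha for glycine; C-alpha fallback (with warning)
#' when C-beta is missing on a non-glycine residue.
#'
#' @param model a [ComplexModel-class].
#' @param residueIdx positional residue index (1..N).
#' @return length-3 numeric coordinate (Angstrom).
#' @export
representativeAtom <- function(model, residueIdx) {
  stopifnot(residueIdx >= 1L, residueIdx <= nResidues(model))
  a <- model@atoms[model@atoms$resIdx == residueIdx, , drop = FALSE]
  aa <- model@residues$aa[residueIdx]
  cb <- which(a$elety == "CB")
  ca <- which(a$elety == "CA")
  if (aa != "G" && length(cb))
    return(as.numeric(a[cb[1L], c("x", "y", "z")]))
  if (length(ca)) {
    if (aa != "G")
      warning("missing C-beta on non-glycine residue; using C-alpha",
              call. = FALSE)
    return(as.numeric(a[ca[1L], c("x", "y", "z")]))
  }
  .err("ppiGeometryError",
       "residue %d has neither C-beta nor C-alpha", residueIdx)
}

#' Detect the cross-entity interface
#'
#' A residue pair (one residue per entity) is part of the interface when
#' the representative atoms (C-beta, or C-alpha for glycine) are within
#' `cutoff` of each other; the boundary is inclusive.
#'
#' @param model a [ComplexModel-class].
#' @param cutoff distance cutoff in Angstrom (default 12).
#' @return an [InterfaceMap-class]; may be empty.
#' @export
findInterface <- function(model, cutoff = 12) {
  rep <- .repCoords(model)
  ent <- .entityVec(model)
  i1 <- which(ent == 1L)
  i2 <- which(ent == 2L)
  d2 <- .cdist2(rep[i1, , drop = FALSE], rep[i2, , drop = FALSE])
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  pairs <- cbind(i = i1[hit[, 1L]], j = i2[hit[, 2L]])
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  new("InterfaceMap", pairs = pairs,
      ifaceSet1 = sort(unique(pairs[, 1L])),
      ifaceSet2 = sort(unique(pairs[, 2L])),
      cutoff = as.numeric(cutoff))
}

.AA_CLASSES <- list(
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
  I = "hydrophobic", M = "hydrophobic",
  F = c("hydrophobic", "aromatic"), W = c("hydrophobic", "aromatic"),
  Y = c("polar", "aromatic"), H = c("polar", "aromatic"),
  S = "polar", T = "polar", N = "polar", Q = "polar", C = "polar",
  K = "charged+", R = "charged+", D = "charged-", E = "charged-",
  G = "special", P = "special", X = "special")

#' Chemical class membership of a residue type
#'
#' Charged set is D/E/K/R; histidine is treated as polar (and aromatic),
#' not charged. A residue can belong to several classes (e.g. F is
#' hydrophobic and aromatic).
#'
#' @param aa one-letter amino-acid code (or X).
#' @return character vector of classes, a subset of `charged+`, `charged-`,
#'   `polar`, `hydrophobic`, `aromatic`, `special`.
#' @export
classifyResidue <- function(aa) {
  cls <- .AA_CLASSES[[toupper(aa)]]
  if (is.null(cls))
    .err("ppiClassificationError", "unknown amino-acid code '%s'", aa)
  cls
}

# Primary (single-membership) class used for contact-pair counting.
.primaryClass <- function(aa) {
  cls <- .AA_CLASSES[[toupper(aa)]]
  if (is.null(cls)) "special"
  else if (any(cls %in% c("charged+", "charged-"))) "charged"
  else if ("polar" %in% cls) "polar"
  else if ("hydrophobic" %in% cls) "hydrophobic"
  else "special"
}

# --- Kabsch-Sander backbone hydrogen bonds -------------------------------

# Amide H placed 1.0 A from N, opposite the previous residue's C=O bond
# (the DSSP convention); chain-start residues and prolines have no donor H.
.amideH <- function(model, bb) {
  r <- model@residues
  n <- nrow(r)
  H <- matrix(NA_real_, n, 3L)
  prev <- c(NA_integer_, seq_len(n - 1L))
  sameChain <- c(FALSE, r$chain[-1L] == r$chain[-n])
  for (i in which(sameChain & r$aa != "P")) {
    p <- prev[i]
    Cp <- bb$C[p, ]; Op <- bb$O[p, ]; Ni <- bb$N[i, ]
    if (anyNA(c(Cp, Op, Ni))) next
    H[i, ] <- Ni + .unit(Cp - Op)
  }
  H
}

# Electrostatic H-bond energies E(donor i, acceptor j) =
# 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol; a bond exists
# when E < -0.5. Returns a logical n x n matrix hb[donor, acceptor].
.hbondMatrix <- function(model, bb = NULL, energies = FALSE) {
  if (is.null(bb)) bb <- .backboneCoords(model)
  r <- model@residues
  n <- nrow(r)
  H <- .amideH(model, bb)
  E <- matrix(0, n, n)
  donors <- which(!is.na(H[, 1L]) & !is.na(bb$N[, 1L]))
  acceptors <- which(!is.na(bb$C[, 1L]) & !is.na(bb$O[, 1L]))
  if (length(donors) && length(acceptors)) {
    q <- 0.084 * 332
    dON <- sqrt(.cdist2(bb$O[acceptors, , drop = FALSE],
                        bb$N[donors, , drop = FALSE]))
    dCH <- sqrt(.cdist2(bb$C[acceptors, , drop = FALSE],
                        H[donors, , drop = FALSE]))
    dOH <- sqrt(.cdist2(bb$O[acceptors, , drop = FALSE],
                        H[donors, , drop = FALSE]))
    dCN <- sqrt(.cdist2(bb$C[acceptors, , drop = FALSE],
                        bb$N[donors, , drop = FALSE]))
    e <- q * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
    e[dON < 0.5 | dOH < 0.5] <- -9.9  # near-contact floor as in DSSP
    E[cbind(rep(donors, each = length(acceptors)),
            rep(acceptors, times = length(donors)))] <- as.numeric(e)
  }
  # no bond to self or sequence neighbors within the same chain
  for (i in seq_len(n)) {
    nb <- i + (-1L:1L)
    nb <- nb[nb >= 1L & nb <= n]
    nb <- nb[r$chain[nb] == r$chain[i]]
    E[i, nb] <- 0
  }
  if (energies) return(E)
  E < -0.5
}

#' Assign secondary structure from backbone geometry
#'
#' Kabsch-Sander-style assignment: backbone hydrogen bonds are scored with
#' the electrostatic energy model (bond when E < -0.5 kcal/mol); helix (H)
#' covers runs of at least two consecutive i -> i+4 bonds, strand (E)
#' covers residues in parallel or antiparallel bridge ladders, everything
#' else (including chain termini and residues with incomplete backbone) is
#' coil (C).
#'
#' @param model a [ComplexModel-class].
#' @return character vector of per-residue labels in `H`, `E`, `C`.
#' @export
assignSecondaryStructure <- function(model) {
  r <- model@residues
  n <- nrow(r)
  lab <- rep("C", n)
  if (n < 5L) return(lab)
  bb <- .backboneCoords(model)
  hb <- .hbondMatrix(model, bb)
  sameChainStep <- function(i, k) {
    j <- i + k
    ok <- j >= 1L & j <= n
    ok[ok] <- r$chain[j[ok]] == r$chain[i[ok]]
    ok
  }
  # 4-turns: donor i+4 -> acceptor i within one chain
  turn4 <- rep(FALSE, n)
  idx <- seq_len(n - 4L)
  okCh <- r$chain[idx] == r$chain[idx + 4L]
  turn4[idx] <- okCh & hb[cbind(idx + 4L, idx)]
  helix <- rep(FALSE, n)
  for (i in which(turn4[-length(turn4)] & turn4[-1L]))
    helix[(i + 1L):min(n, i + 5L)] <- TRUE
  # bridges (parallel / antiparallel), sequence separation >= 3 or
  # different chains
  strand <- rep(FALSE, n)
  hbAt <- function(i, j) {
    ok <- i >= 1L & i <= n & j >= 1L & j <= n
    out <- rep(FALSE, length(i))
    out[ok] <- hb[cbind(i[ok], j[ok])]
    out
  }
  cand <- which(hb, arr.ind = TRUE)  # donor, acceptor pairs seed search
  seen <- unique(rbind(cand, cand[, 2:1, drop = FALSE]))
  if (nrow(seen)) {
    i <- seen[, 1L]; j <- seen[, 2L]
    keep <- abs(i - j) >= 3L | r$chain[i] != r$chain[j]
    i <- i[keep]; j <- j[keep]
    # hb[donor, acceptor]; the classic bridge patterns, with bond(x, y)
    # meaning CO(x) accepting from NH(y), i.e. hb[y, x]
    anti <- (hbAt(j, i) & hbAt(i, j)) |
      (hbAt(j + 1L, i - 1L) & hbAt(i + 1L, j - 1L) &
         sameChainStep(i, -1L) & sameChainStep(i, 1L) &
         sameChainStep(j, -1L) & sameChainStep(j, 1L))
    para <- (hbAt(j, i - 1L) & hbAt(i + 1L, j) &
               sameChainStep(i, -1L) & sameChainStep(i, 1L)) |
      (hbAt(i, j - 1L) & hbAt(j + 1L, i) &
         sameChainStep(j, -1L) & sameChainStep(j, 1L))
    bridged <- unique(c(i[anti | para], j[anti | para]))
    strand[bridged] <- TRUE
  }
  lab[strand] <- "E"
  lab[helix & !strand] <- "H"
  lab
}
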