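# Docking-model quality: Kabsch superposition, Fnat, iRMS/LRMS, DockQ.

# Constants of the composite quality score (pinned): contact cutoff 5 A,
# interface definition 10 A (heavy atom), iRMS scale 1.5 A, LRMS scale
# 8.5 A, acceptability threshold 0.23.
.DOCKQ_CONTACT <- 5.0
.DOCKQ_IFACE <- 10.0
.DOCKQ_IRMS_SCALE <- 1.5
.DOCKQ_LRMS_SCALE <- 8.5
DOCKQ_ACCEPTABLE <- 0.23

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation + translation mapping `coordsB` onto `coordsA`.
#'
#' @param coordsA,coordsB n x 3 matrices of paired coordinates (n >= 3).
#' @return a [SuperpositionResult-class].
#' @export
kabschSuperpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA)
  coordsB <- as.matrix(coordsB)
  if (nrow(coordsA) != nrow(coordsB) || ncol(coordsA) != 3L ||
      ncol(coordsB) != 3L)
    .err("ppiGeometryError", "coordinate sets must be matched n x 3")
  if (nrow(coordsA) < 3L)
    .err("ppiGeometryError", "superposition needs at least 3 points")
  k <- .kabschCore(coordsA, coordsB)
  # degenerate (collinear) sets leave the rotation underdetermined
  if (sum(k$singular > 1e-8 * max(k$singular, 1e-12)) < 2L)
    .err("ppiGeometryError", "degenerate (collinear) coordinate set")
  new("SuperpositionResult", rotation = k$R,
      translation = as.numeric(k$t), rmsd = k$rmsd)
}

#' Apply a superposition transform
#'
#' @param sup a [SuperpositionResult-class].
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
applySuperposition <- function(sup, coords) {
  .applyTransform(as.matrix(coords), sup@rotation, sup@translation)
}

# Pair model/native residues by (chain, resno, ins); returns index map
# (model idx for each native idx, NA where unmatched).
.correspondence <- function(model, native) {
  keyM <- with(model@residues, paste(chain, resno, ins, sep = "\r"))
  keyN <- with(native@residues, paste(chain, resno, ins, sep = "\r"))
  match(keyN, keyM)
}

# Cross-entity residue contact pairs at a heavy-atom distance cutoff,
# as a character key set "i:j" in native residue indices.
.contactPairs <- function(model, cutoff) {
  a <- model@atoms
  ent <- .entityVec(model)
  atomEnt <- ent[a$resIdx]
  A <- which(atomEnt == 1L)
  B <- which(atomEnt == 2L)
  D2 <- .cdist2(as.matrix(a[A, c("x", "y", "z")]),
                as.matrix(a[B, c("x", "y", "z")]))
  hit <- which(D2 <= cutoff^2, arr.ind = TRUE)
  unique(paste(a$resIdx[A[hit[, 1L]]], a$resIdx[B[hit[, 2L]]], sep = ":"))
}

#' Fraction of native contacts reproduced by a model
#'
#' Native contacts are cross-entity residue pairs with any heavy-atom
#' distance within 5 A in the native structure; Fnat is the fraction of
#' those preserved (same residue pair in contact) in the model.
#'
#' @param model,native [ComplexModel-class] objects with residues pairable
#'   by chain + author numbering.
#' @return fraction in \[0, 1\].
#' @export
fnat <- function(model, native) {
  corr <- .correspondence(model, native)
  natPairs <- .contactPairs(native, .DOCKQ_CONTACT)
  if (!length(natPairs))
    .err("ppiQualityError", "native structure has no cross-entity contacts")
  modPairs <- .contactPairs(model, .DOCKQ_CONTACT)
  # translate model pairs into native indexing
  back <- match(seq_len(nResidues(model)), corr)  # native idx per model idx
  split2 <- function(p) do.call(rbind, strsplit(p, ":", fixed = TRUE))
  mp <- split2(modPairs)
  i <- back[as.integer(mp[, 1L])]
  j <- back[as.integer(mp[, 2L])]
  ok <- !is.na(i) & !is.na(j)
  modKeys <- paste(i[ok], j[ok], sep = ":")
  sum(natPairs %in% modKeys) / length(natPairs)
}

.backboneXyz <- function(model, residueIdx) {
  a <- model@atoms
  sel <- a$resIdx %in% residueIdx & a$elety %in% c("N", "CA", "C", "O")
  a <- a[sel, , drop = FALSE]
  o <- order(a$resIdx, match(a$elety, c("N", "CA", "C", "O")))
  a <- a[o, , drop = FALSE]
  list(xyz = as.matrix(a[, c("x", "y", "z")]),
       key = paste(a$resIdx, a$elety))
}

# Matched backbone coordinate pair (native, model) over given native
# residue indices.
.matchedBackbone <- function(model, native, natIdx, corr) {
  modIdx <- corr[natIdx]
  keep <- !is.na(modIdx)
  natIdx <- natIdx[keep]
  modIdx <- modIdx[keep]
  nb <- .backboneXyz(native, natIdx)
  mb <- .backboneXyz(model, modIdx)
  # align atom lists through the residue correspondence
  natKey <- nb$key
  mapRes <- stats::setNames(natIdx, modIdx)
  modKeyAsNat <- vapply(strsplit(mb$key, " "), function(p)
    paste(mapRes[p[1L]], p[2L]), "")
  common <- intersect(natKey, modKeyAsNat)
  list(native = nb$xyz[match(common, natKey), , drop = FALSE],
       model = mb$xyz[match(common, modKeyAsNat), , drop = FALSE])
}

#' Composite docking-model quality score
#'
#' DockQ = (Fnat + 1/(1 + (iRMS/1.5)^2) + 1/(1 + (LRMS/8.5)^2)) / 3, with
#' iRMS the backbone RMSD over native-interface residues (10 A heavy-atom
#' interface definition) after superposing on those residues, and LRMS the
#' ligand backbone RMSD after superposing on the receptor (the larger
#' entity).
#'
#' @param model,native [ComplexModel-class] objects.
#' @return list with `dockq`, `fnat`, `irms`, `lrms`.
#' @export
dockq <- function(model, native) {
  corr <- .correspondence(model, native)
  fn <- fnat(model, native)
  # native interface residues at the 10 A heavy-atom definition
  ifPairs <- .contactPairs(native, .DOCKQ_IFACE)
  ifRes <- sort(unique(as.integer(unlist(strsplit(ifPairs, ":",
                                                  fixed = TRUE)))))
  ib <- .matchedBackbone(model, native, ifRes, corr)
  if (nrow(ib$native) < 3L)
    .err("ppiQualityError", "too few matched interface backbone atoms")
  irms <- .kabschCore(ib$native, ib$model)$rmsd
  # receptor = larger entity (ties to entity 1)
  entN <- .entityVec(native)
  recEnt <- if (sum(entN == 2L) > sum(entN == 1L)) 2L else 1L
  ligEnt <- 3L - recEnt
  rb <- .matchedBackbone(model, native,
                         native@residues$idx[entN == recEnt], corr)
  k <- .kabschCore(rb$native, rb$model)
  lb <- .matchedBackbone(model, native,
                         native@residues$idx[entN == ligEnt], corr)
  ligModelAligned <- .applyTransform(lb$model, k$R, k$t)
  lrms <- sqrt(mean(rowSums((ligModelAligned - lb$native)^2)))
  list(dockq = dockqCombine(fn, irms, lrms), fnat = fn, irms = irms,
       lrms = lrms)
}

#' Combine the three quality metrics into the composite score
#'
#' @param fnat fraction of native contacts in \[0, 1\].
#' @param irms interface backbone RMSD (Angstrom).
#' @param lrms ligand backbone RMSD (Angstrom).
#' @return composite score in \[0, 1\].
#' @export
#' @examples
#' dockqCombine(1, 0, 0)        # 1: identical model
#' dockqCombine(0.5, 1.5, 8.5)  # 0.5: both RMSD sigmoids half-saturated
dockqCombine <- function(fnat, irms, lrms) {
  (fnat + 1 / (1 + (irms / .DOCKQ_IRMS_SCALE)^2) +
     1 / (1 + (lrms / .DOCKQ_LRMS_SCALE)^2)) / 3
}

#' Acceptability filter on DockQ
#'
#' @param dockqScore score in \[0, 1\].
#' @param threshold acceptability threshold (default 0.23); the boundary is
#'   inclusive.
#' @return logical.
#' @export
isAcceptable <- function(dockqScore, threshold = DOCKQ_ACCEPTABLE) {
  stopifnot(all(dockqScore >= 0 & dockqScore <= 1))
  dockqScore >= threshold
}
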