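# Compelling-decoy construction: TM-score analog ranking and rigid
# analog-onto-template placement.

#' TM-score normalization scale
#'
#' d0(L) = 1.24 (L - 15)^(1/3) - 1.8, floored at 0.5 A.
#'
#' @param lref reference length (residues, >= 15).
#' @return d0 in Angstrom.
#' @export
tmD0 <- function(lref) {
  pmax(0.5, 1.24 * (pmax(lref - 15, 0))^(1 / 3) - 1.8)
}

.caOf <- function(x) {
  if (is(x, "ProteinStructure")) caCoords(x)
  else if (is.matrix(x)) x
  else .err("ppiLengthError", "expected ProteinStructure or N x 3 matrix")
}

# Score a gapless offset alignment after a given superposition transform;
# score is over the full overlap, normalized by Lref.
.tmScoreOffset <- function(Q, R, offset, d0) {
  lq <- nrow(Q); lr <- nrow(R)
  k <- max(1L, 1L - offset):min(lq, lr - offset)
  if (length(k) < 3L) return(NULL)
  list(q = k, r = k + offset)
}

#' Template-modeling score between two chains
#'
#' TM = (1/Lref) * sum over aligned residues of 1/(1 + (d_i/d0)^2), with
#' d0 from [tmD0()] of the reference length. The alignment is found from
#' gapless fragment-superposition seeds (length-20 windows, stride 5)
#' refined by iterating superposition on the close subset; the best seed
#' wins. Normalization is by the reference (second argument), so the score
#' is not symmetric in its arguments.
#'
#' @param query,reference [ProteinStructure-class] objects or N x 3
#'   C-alpha matrices; both need >= 15 residues.
#' @return TM-score in (0, 1].
#' @export
tmScore <- function(query, reference) {
  Q <- .caOf(query)
  R <- .caOf(reference)
  if (nrow(Q) < 15L || nrow(R) < 15L)
    .err("ppiLengthError",
         "TM-score requires >= 15 residues (got %d and %d)", nrow(Q),
         nrow(R))
  lr <- nrow(R)
  d0 <- tmD0(lr)
  win <- 20L
  qStarts <- unique(c(seq(1L, max(1L, nrow(Q) - win + 1L), 5L),
                      max(1L, nrow(Q) - win + 1L)))
  rStarts <- unique(c(seq(1L, max(1L, lr - win + 1L), 5L),
                      max(1L, lr - win + 1L)))
  best <- 0
  for (qs in qStarts) for (rs in rStarts) {
    w <- min(win, nrow(Q) - qs + 1L, lr - rs + 1L)
    if (w < 5L) next
    offset <- rs - qs
    al <- .tmScoreOffset(Q, R, offset, d0)
    if (is.null(al)) next
    # seed transform from the fragment
    k <- .kabschCore(R[rs:(rs + w - 1L), , drop = FALSE],
                     Q[qs:(qs + w - 1L), , drop = FALSE])
    sel <- seq_along(al$q) %in% which(al$q >= qs & al$q <= qs + w - 1L)
    for (iter in 1:20) {
      Qt <- .applyTransform(Q[al$q, , drop = FALSE], k$R, k$t)
      d <- sqrt(rowSums((Qt - R[al$r, , drop = FALSE])^2))
      sc <- sum(1 / (1 + (d / d0)^2)) / lr
      if (sc > best) best <- sc
      dcut <- d0
      repeat {
        newSel <- d < dcut
        if (sum(newSel) >= 3L) break
        dcut <- dcut + 0.5
      }
      if (identical(newSel, sel)) break
      sel <- newSel
      k <- .kabschCore(R[al$r[sel], , drop = FALSE],
                       Q[al$q[sel], , drop = FALSE])
    }
  }
  max(best, 1e-6)
}

# Full TM-score table over a library (named list of ProteinStructure):
# tm[q, ref] normalized by ref. Used by exhaustive-search tests too.
.tmTable <- function(library) {
  ids <- names(library)
  ca <- lapply(library, .caOf)
  tm <- matrix(NA_real_, length(ids), length(ids),
               dimnames = list(ids, ids))
  for (q in ids) for (r in ids) {
    if (q == r) { tm[q, r] <- 1; next }
    tm[q, r] <- tmScore(ca[[q]], ca[[r]])
  }
  tm
}

#' Nearest structural analog of a protein
#'
#' Ranks all library members (excluding the protein itself and its binding
#' partner in the pairing index) by TM-score normalized by the template
#' protein's length; TM ties within 1e-6 are broken by lexicographic id.
#'
#' @param proteinId id of the template protein.
#' @param library named list of [ProteinStructure-class] objects.
#' @param pairingIndex data.frame of active pairings with columns `id1`,
#'   `id2` (used to exclude the template's own partner(s)).
#' @param tmTable optional precomputed TM matrix (`tm[query, ref]`); the
#'   ranking uses column `proteinId`.
#' @param rank 1 for the best analog, 2 for the second best.
#' @return list with `analogId`, `tm`, `rankUsed`.
#' @export
nearestAnalog <- function(proteinId, library, pairingIndex = NULL,
                          tmTable = NULL, rank = 1L) {
  ids <- names(library)
  if (!proteinId %in% ids)
    .err("ppiAnalogError", "protein '%s' not in library", proteinId)
  if (is.null(tmTable)) tmTable <- .tmTable(library)
  partners <- character(0)
  if (!is.null(pairingIndex)) {
    partners <- c(pairingIndex$id2[pairingIndex$id1 == proteinId],
                  pairingIndex$id1[pairingIndex$id2 == proteinId])
  }
  cand <- setdiff(ids, c(proteinId, partners))
  if (length(cand) < rank)
    .err("ppiAnalogError", "no candidate analog for '%s' at rank %d",
         proteinId, rank)
  tm <- tmTable[cand, proteinId]
  o <- order(-round(tm / 1e-6) * 1e-6, cand)
  list(analogId = cand[o[rank]], tm = unname(tm[o[rank]]),
       rankUsed = if (rank == 1L) "best" else "second_best")
}

.isActivePairing <- function(idA, idB, pairingIndex) {
  any((pairingIndex$id1 == idA & pairingIndex$id2 == idB) |
        (pairingIndex$id1 == idB & pairingIndex$id2 == idA))
}

#' Build a decoy recipe for one template complex
#'
#' Replaces both component proteins of an active complex by their closest
#' structural analogs. If the chosen analog pair itself reconstitutes an
#' active pairing, the second-best analog is substituted in one slot
#' (whichever single-slot substitution keeps the higher combined TM-score),
#' falling back to second-best in both slots.
#'
#' @param templateId id of the template complex (row of `pairingIndex`).
#' @param library named list of [ProteinStructure-class] objects.
#' @param pairingIndex data.frame with columns `complex_id`, `id1`, `id2`.
#' @param tmTable optional precomputed TM matrix.
#' @return list with `analog1`, `analog2` (each as from
#'   [nearestAnalog()]).
#' @export
decoyPairing <- function(templateId, library, pairingIndex,
                         tmTable = NULL) {
  row <- pairingIndex[pairingIndex$complex_id == templateId, , drop = FALSE]
  if (nrow(row) != 1L)
    .err("ppiAnalogError", "template complex '%s' not in pairing index",
         templateId)
  if (is.null(tmTable)) tmTable <- .tmTable(library)
  a1 <- nearestAnalog(row$id1, library, pairingIndex, tmTable, 1L)
  a2 <- nearestAnalog(row$id2, library, pairingIndex, tmTable, 1L)
  if (.isActivePairing(a1$analogId, a2$analogId, pairingIndex)) {
    s1 <- nearestAnalog(row$id1, library, pairingIndex, tmTable, 2L)
    s2 <- nearestAnalog(row$id2, library, pairingIndex, tmTable, 2L)
    opts <- list(list(a1, s2, tm = a1$tm + s2$tm),
                 list(s1, a2, tm = s1$tm + a2$tm),
                 list(s1, s2, tm = s1$tm + s2$tm))
    ok <- vapply(opts, function(o)
      !.isActivePairing(o[[1L]]$analogId, o[[2L]]$analogId, pairingIndex),
      TRUE)
    if (!any(ok))
      .err("ppiAnalogError",
           "cannot build a non-active decoy pairing for '%s'", templateId)
    pick <- which(ok)[which.max(vapply(opts[ok], `[[`, 0, "tm"))]
    a1 <- opts[[pick]][[1L]]
    a2 <- opts[[pick]][[2L]]
  }
  list(analog1 = a1, analog2 = a2)
}

#' Build a decoy complex from a template and two analogs
#'
#' Rigidly places each analog by superposing its C-alpha trace onto the
#' corresponding template component (gapless overlap from the start of
#' both chains), yielding the crude decoy structure for inspection and the
#' component sequences for downstream re-prediction.
#'
#' @param template a [ComplexModel-class] (the active complex).
#' @param analog1,analog2 [ProteinStructure-class] analogs replacing
#'   entity 1 and entity 2.
#' @param analogInfo optional list from [decoyPairing()] carrying
#'   TM-scores/ranks for the recipe.
#' @return list with `decoy` ([ComplexModel-class]), `sequences` (named
#'   character), and `recipe` ([DecoyRecipe-class]).
#' @export
buildDecoy <- function(template, analog1, analog2, analogInfo = NULL) {
  placeOne <- function(analog, entity, chainId) {
    res <- template@residues
    idx <- res$idx[res$entity == entity]
    tCa <- .repCaOfEntity(template, entity)
    aCa <- caCoords(analog)
    n <- min(nrow(tCa), nrow(aCa))
    if (n < 3L)
      .err("ppiRecipeError", "analog too short to superpose")
    sup <- kabschSuperpose(tCa[seq_len(n), , drop = FALSE],
                           aCa[seq_len(n), , drop = FALSE])
    a <- analog@atoms
    xyz <- applySuperposition(sup, as.matrix(a[, c("x", "y", "z")]))
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
    a$chain <- chainId
    list(atoms = a, sup = sup)
  }
  p1 <- placeOne(analog1, 1L, "A")
  p2 <- placeOne(analog2, 2L, "B")
  decoy <- ComplexModel(rbind(p1$atoms, p2$atoms),
                        complexId = paste0("decoy_", template@complexId),
                        modelRank = 1L,
                        entitySpec = c(A = 1L, B = 2L))
  seqs <- c(sequenceOf(analog1), sequenceOf(analog2))
  names(seqs) <- c(analog1@id, analog2@id)
  info <- function(slot, dflt) {
    if (is.null(analogInfo)) dflt else analogInfo[[slot]]
  }
  a1 <- info("analog1", list(analogId = analog1@id, tm = 1,
                             rankUsed = "best"))
  a2 <- info("analog2", list(analogId = analog2@id, tm = 1,
                             rankUsed = "best"))
  recipe <- new("DecoyRecipe", templateComplexId = template@complexId,
                analogId1 = a1$analogId, analogId2 = a2$analogId,
                tmScore1 = a1$tm, tmScore2 = a2$tm,
                rankUsed1 = a1$rankUsed, rankUsed2 = a2$rankUsed,
                transforms = list(p1$sup, p2$sup))
  list(decoy = decoy, sequences = seqs, recipe = recipe)
}

.repCaOfEntity <- function(model, entity) {
  a <- model@atoms
  res <- model@residues
  idx <- res$idx[res$entity == entity]
  sel <- a$resIdx %in% idx & a$elety == "CA"
  as.matrix(a[sel, c("x", "y", "z")])
}

#' Size-bias report over a set of decoy recipes
#'
#' Nearest-analog substitution slightly favors larger proteins (larger
#' analogs tend to have higher TM-score to a template). This reports the
#' distribution of analog-length / template-length ratios, and optionally
#' flags manifest features that correlate with total length on the decoy
#' feature table (such features must not be in the manifest).
#'
#' @param recipes list of [DecoyRecipe-class] objects.
#' @param library named list of [ProteinStructure-class] objects.
#' @param pairingIndex data.frame with columns `complex_id`, `id1`, `id2`.
#' @param featureTable optional [FeatureTable-class] of decoy rows with a
#'   `total_len` attribute column to correlate against.
#' @param corThreshold absolute-correlation flag threshold (default 0.5).
#' @return list with `ratios` (numeric), `mean_ratio`, `frac_larger`, and
#'   `flagged_features` (character).
#' @export
sizeBiasReport <- function(recipes, library, pairingIndex,
                           featureTable = NULL, totalLen = NULL,
                           corThreshold = 0.5) {
  if (!length(recipes))
    .err("ppiDataError", "size-bias report needs at least one recipe")
  lenOf <- function(id) nResidues(library[[id]])
  ratios <- unlist(lapply(recipes, function(r) {
    row <- pairingIndex[pairingIndex$complex_id == r@templateComplexId, ]
    c(lenOf(r@analogId1) / lenOf(row$id1),
      lenOf(r@analogId2) / lenOf(row$id2))
  }))
  flagged <- character(0)
  if (!is.null(featureTable) && !is.null(totalLen)) {
    d <- featureData(featureTable)
    feats <- intersect(names(d), featureNames(manifestVersion(featureTable)))
    for (f in feats) {
      v <- d[[f]]
      if (stats::sd(v) < 1e-12) next
      if (abs(stats::cor(v, totalLen)) > corThreshold)
        flagged <- c(flagged, f)
    }
  }
  list(ratios = unname(ratios), mean_ratio = mean(ratios),
       frac_larger = mean(ratios > 1), flagged_features = flagged)
}
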