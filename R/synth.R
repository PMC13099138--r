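# Synthetic fixtures: idealized chains (NeRF backbone construction),
# docked/clashed/separated complexes, confidence bundles with controllable
# interchain-PAE signal, and labeled feature tables with stated
# class-conditional effect sizes. All generators are seed-deterministic.

.IDEAL_PHI_PSI <- list(H = c(-57, -47), E = c(-139, 135))
.BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231,
           CA_CB = 1.521)
.ANGLE <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7,
            CA_C_O = 120.5, N_CA_CB = 110.4)

.withSeed <- function(seed, expr) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  expr
}

#' Build an idealized protein chain
#'
#' Backbone (N, CA, C, O) plus C-beta built from ideal bond geometry and
#' per-residue phi/psi dictated by the secondary-structure pattern: helix
#' -57/-47, strand -139/135, coil randomized within the broad allowed
#' region. Poly-alanine by default; an explicit sequence (one-letter)
#' controls residue identities (glycines get no C-beta).
#'
#' @param length number of residues (>= 15).
#' @param ssPattern string over H/E/C, recycled to `length` (single
#'   character allowed).
#' @param seed integer seed (used for coil torsions).
#' @param id structure id (also the chain id).
#' @param sequence optional one-letter sequence of `length` residues.
#' @return a [ProteinStructure-class].
#' @export
makeChain <- function(length, ssPattern = "H", seed = 1L, id = "A",
                      sequence = NULL) {
  if (length < 15L)
    .err("ppiLengthError", "chain length must be >= 15 (got %d)", length)
  ss <- strsplit(ssPattern, "")[[1]]
  if (!all(ss %in% c("H", "E", "C")))
    .err("ppiConfigError", "ssPattern must be over {H, E, C}")
  ss <- rep_len(ss, length)
  if (is.null(sequence)) sequence <- strrep("A", length)
  aa <- strsplit(sequence, "")[[1]]
  if (base::length(aa) != length)
    .err("ppiConfigError", "sequence length must equal chain length")
  .withSeed(seed, {
    phi <- numeric(length)
    psi <- numeric(length)
    for (i in seq_len(length)) {
      if (ss[i] == "C") {
        phi[i] <- stats::runif(1, -150, -60)
        psi[i] <- stats::runif(1, 90, 180)
      } else {
        phi[i] <- .IDEAL_PHI_PSI[[ss[i]]][1L]
        psi[i] <- .IDEAL_PHI_PSI[[ss[i]]][2L]
      }
    }
    N <- CA <- C <- O <- CB <- matrix(NA_real_, length, 3L)
    N[1L, ] <- c(0, 0, 0)
    CA[1L, ] <- c(.BOND["N_CA"], 0, 0)
    ang <- .ANGLE["N_CA_C"] * pi / 180
    C[1L, ] <- CA[1L, ] + .BOND["CA_C"] * c(-cos(ang), sin(ang), 0)
    for (i in seq_len(length)) {
      if (i > 1L) {
        N[i, ] <- .placeAtom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                             .BOND["C_N"], .ANGLE["CA_C_N"], psi[i - 1L])
        CA[i, ] <- .placeAtom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                              .BOND["N_CA"], .ANGLE["C_N_CA"], 180)
        C[i, ] <- .placeAtom(C[i - 1L, ], N[i, ], CA[i, ],
                             .BOND["CA_C"], .ANGLE["N_CA_C"], phi[i])
      }
      if (aa[i] != "G")
        CB[i, ] <- .placeAtom(C[i, ], N[i, ], CA[i, ],
                              .BOND["CA_CB"], .ANGLE["N_CA_CB"], 122.6)
    }
    # carbonyl O: anti to the next amide nitrogen (psi - 180 torsion)
    for (i in seq_len(length))
      O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ],
                           .BOND["C_O"], .ANGLE["CA_C_O"], psi[i] - 180)
    rows <- list()
    for (i in seq_len(length)) {
      at <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ],
                  CB = CB[i, ])
      at <- at[!is.na(at[, 1L]), , drop = FALSE]
      rows[[i]] <- data.frame(chain = id, resno = i, ins = "",
                              resid = .aa123(aa[i]),
                              elety = rownames(at),
                              element = substr(rownames(at), 1L, 1L),
                              x = at[, 1L], y = at[, 2L], z = at[, 3L],
                              b = 0, stringsAsFactors = FALSE)
    }
    ProteinStructure(do.call(rbind, rows), id = id)
  })
}

# Untwisted (exact two-fold screw) strand torsions used for flat sheet
# fixtures; the generic strand state in makeChain keeps the textbook
# -139/135 pair, which carries the natural beta twist.
.FLAT_STRAND <- c(phi = -149, psi = 147)

.canonicalStrandAtoms <- function(n, id = "A") {
  phi <- rep(.FLAT_STRAND["phi"], n)
  psi <- rep(.FLAT_STRAND["psi"], n)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(.BOND["N_CA"], 0, 0)
  ang <- .ANGLE["N_CA_C"] * pi / 180
  C[1L, ] <- CA[1L, ] + .BOND["CA_C"] * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- .placeAtom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                           .BOND["C_N"], .ANGLE["CA_C_N"], psi[i - 1L])
      CA[i, ] <- .placeAtom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            .BOND["N_CA"], .ANGLE["C_N_CA"], 180)
      C[i, ] <- .placeAtom(C[i - 1L, ], N[i, ], CA[i, ],
                           .BOND["CA_C"], .ANGLE["N_CA_C"], phi[i])
    }
    CB[i, ] <- .placeAtom(C[i, ], N[i, ], CA[i, ],
                          .BOND["CA_CB"], .ANGLE["N_CA_CB"], 122.6)
  }
  for (i in seq_len(n))
    O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ],
                         .BOND["C_O"], .ANGLE["CA_C_O"], psi[i] - 180)
  # canonical frame: strand axis -> +x, pleat plane -> xy
  u <- .unit(CA[n, ] - CA[1L, ])
  w <- CA[2L, ] - CA[1L, ]
  w <- .unit(w - sum(w * u) * u)
  Rc <- rbind(u, w, .cross3(u, w))
  toCanon <- function(M) sweep(M, 2L, CA[1L, ]) %*% t(Rc)
  N <- toCanon(N); CAc <- toCanon(CA); C <- toCanon(C)
  O <- toCanon(O); CB <- toCanon(CB)
  rows <- list()
  for (i in seq_len(n)) {
    at <- rbind(N = N[i, ], CA = CAc[i, ], C = C[i, ], O = O[i, ],
                CB = CB[i, ])
    rows[[i]] <- data.frame(chain = id, resno = i, ins = "",
                            resid = "ALA", elety = rownames(at),
                            element = substr(rownames(at), 1L, 1L),
                            x = at[, 1L], y = at[, 2L], z = at[, 3L],
                            b = 0, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Idealized flat antiparallel two-strand sheet
#'
#' Two untwisted strands placed in hydrogen-bond registry (second strand
#' flipped end-for-end and offset into the ladder plane); deterministic,
#' used to exercise strand assignment and beta-composition features.
#'
#' @param length residues per strand (>= 15).
#' @param complexId id for the resulting model.
#' @return a [ComplexModel-class] with the two strands as the two
#'   entities.
#' @export
makeSheetPair <- function(length = 16L, complexId = "sheet") {
  a1 <- .canonicalStrandAtoms(length, "A")
  xyz <- as.matrix(a1[, c("x", "y", "z")])
  caLast <- xyz[a1$elety == "CA", ][length, 1L]
  R <- diag(c(-1, -1, 1))          # 180 degrees about z: antiparallel
  off <- c(caLast + 2.4, 3.2, 0)   # ladder registry (pinned)
  x2 <- sweep(xyz %*% R, 2L, off, "+")
  b2 <- a1
  b2[, c("x", "y", "z")] <- x2
  b2$chain <- "B"
  ComplexModel(rbind(a1, b2), complexId = complexId,
               entitySpec = c(A = 1L, B = 2L))
}

.randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

.chainRepCoords <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  ukey <- unique(key)
  out <- matrix(NA_real_, base::length(ukey), 3L)
  for (k in seq_along(ukey)) {
    a <- atoms[key == ukey[k], , drop = FALSE]
    row <- if ("CB" %in% a$elety && a$resid[1L] != "GLY")
      a[a$elety == "CB", ][1L, ] else a[a$elety == "CA", ][1L, ]
    out[k, ] <- as.numeric(row[c("x", "y", "z")])
  }
  out
}

#' Build a two-entity synthetic complex in a controlled pose
#'
#' Combines single-chain structures into a complex and rigidly places the
#' second entity along a seeded approach direction so the pose satisfies
#' its defining geometric predicate: docked (minimum cross-entity
#' representative-atom distance within 4-8 Angstrom, no heavy-atom overlap
#' under 2.5 Angstrom), clashed (at least 5 heavy-atom pairs under 2.0
#' Angstrom), or separated (minimum cross-entity distance above 30
#' Angstrom). The predicate is asserted post-generation.
#'
#' @param chains1,chains2 lists of [ProteinStructure-class] objects
#'   forming entity 1 and entity 2.
#' @param mode `"docked"`, `"clashed"`, or `"separated"`.
#' @param seed integer seed (orientation draw).
#' @param complexId,modelRank identifiers for the result.
#' @param maxRetries orientation retries before a generation error.
#' @return a [ComplexModel-class].
#' @export
makeComplex <- function(chains1, chains2,
                        mode = c("docked", "clashed", "separated"),
                        seed = 1L, complexId = "synth", modelRank = 1L,
                        maxRetries = 25L) {
  mode <- match.arg(mode)
  if (is(chains1, "ProteinStructure")) chains1 <- list(chains1)
  if (is(chains2, "ProteinStructure")) chains2 <- list(chains2)
  relabel <- function(chains, letters_) {
    out <- list()
    for (k in seq_along(chains)) {
      a <- chains[[k]]@atoms
      a$chain <- letters_[k]
      out[[k]] <- a
    }
    do.call(rbind, out)
  }
  n1 <- base::length(chains1)
  a1 <- relabel(chains1, LETTERS[seq_len(n1)])
  a2 <- relabel(chains2, LETTERS[n1 + seq_along(chains2)])
  center <- function(a) {
    xyz <- as.matrix(a[, c("x", "y", "z")])
    sweep(xyz, 2L, colMeans(xyz))
  }
  xyz1 <- center(a1)
  a1[, c("x", "y", "z")] <- xyz1
  rep1 <- .chainRepCoords(a1)
  heavy1 <- xyz1
  .withSeed(seed, {
    for (attempt in seq_len(maxRetries)) {
      R <- if (attempt == 1L) diag(3) else .randomRotation()
      xyz2 <- center(a2) %*% R
      b2 <- a2
      b2[, c("x", "y", "z")] <- xyz2
      rep2 <- .chainRepCoords(b2)
      heavy2 <- xyz2
      span <- max(sqrt(rowSums(heavy1^2))) + max(sqrt(rowSums(heavy2^2)))
      if (mode == "separated") {
        t <- span + 40
        cand <- sweep(heavy2, 2L, c(t, 0, 0), "+")
        minD <- sqrt(min(.cdist2(heavy1, cand)))
        if (minD > 30) return(.finishComplex(a1, b2, c(t, 0, 0), n1,
                                             complexId, modelRank))
        next
      }
      ts <- seq(span + 5, 0, by = -0.25)
      found <- NULL
      for (t in ts) {
        off <- c(t, 0, 0)
        minRep <- sqrt(min(.cdist2(rep1, sweep(rep2, 2L, off, "+"))))
        d2h <- .cdist2(heavy1, sweep(heavy2, 2L, off, "+"))
        if (mode == "docked") {
          # advance to the tightest placement that still has no heavy-atom
          # overlap, so the pose carries real atomic contacts
          if (minRep < 4 || sqrt(min(d2h)) < 2.5) break
          if (minRep <= 8) found <- off
        } else {  # clashed
          nClash <- sum(d2h < 2.0^2)
          if (nClash >= 5L) { found <- off; break }
          if (t == 0) break
        }
      }
      if (!is.null(found))
        return(.finishComplex(a1, b2, found, n1, complexId, modelRank))
    }
    .err("ppiGenerationError",
         "could not realize a %s pose after %d orientations", mode,
         maxRetries)
  })
}

.finishComplex <- function(a1, b2, offset, n1, complexId, modelRank) {
  b2[, c("x", "y", "z")] <-
    sweep(as.matrix(b2[, c("x", "y", "z")]), 2L, offset, "+")
  atoms <- rbind(a1, b2)
  chains <- unique(atoms$chain)
  spec <- stats::setNames(ifelse(seq_along(chains) <= n1, 1L, 2L), chains)
  ComplexModel(atoms, complexId = complexId, modelRank = modelRank,
               entitySpec = spec)
}

#' Generate a synthetic confidence bundle
#'
#' Emulates the signal the classifier consumes: intra-entity PAE around 2,
#' cross-entity PAE around 4 (confident interface) or 25 (uncertain),
#' everything clipped to \[0, 31.75\]; pLDDT uniform in 85-95; iPTM 0.8 or
#' 0.2 per scenario.
#'
#' @param model the paired [ComplexModel-class].
#' @param scenario `"confident_interface"` or `"uncertain_interface"`.
#' @param noiseSd Gaussian noise standard deviation (Angstrom).
#' @param seed integer seed.
#' @return a [ConfidenceBundle-class].
#' @export
makeConfidence <- function(model,
                           scenario = c("confident_interface",
                                        "uncertain_interface"),
                           noiseSd = 1, seed = 1L) {
  scenario <- match.arg(scenario)
  n <- nResidues(model)
  ent <- .entityVec(model)
  .withSeed(seed, {
    crossMu <- if (scenario == "confident_interface") 4 else 25
    cross <- outer(ent, ent, "!=")
    paeM <- matrix(2 + stats::rnorm(n * n, 0, noiseSd), n, n)
    paeM[cross] <- crossMu + stats::rnorm(sum(cross), 0, noiseSd)
    diag(paeM) <- 0.3
    paeM[paeM < 0] <- 0
    paeM[paeM > PAE_CEILING] <- PAE_CEILING
    pl <- stats::runif(n, 85, 95)
    if (scenario == "confident_interface")
      ConfidenceBundle(pl, paeM, ptm = 0.85, iptm = 0.8)
    else
      ConfidenceBundle(pl, paeM, ptm = 0.6, iptm = 0.2)
  })
}

#' Generate a labeled synthetic feature table
#'
#' Balanced active/decoy labels at the complex level; the first
#' `nInformative` manifest features are drawn class-conditionally with the
#' stated standardized mean difference (`effectSize`), the rest are
#' label-independent nuisance; rows within a complex share a random
#' complex effect (variance 0.25 of a unit total), emulating the
#' correlation between the five models of one prediction.
#'
#' @param nComplexes number of complexes (>= 10).
#' @param modelsPerComplex rows per complex (default 5).
#' @param effectSize standardized mean difference of informative features.
#' @param seed integer seed.
#' @param nInformative number of informative features (default 10).
#' @return a [FeatureTable-class].
#' @export
makeFeatureTable <- function(nComplexes, modelsPerComplex = 5L,
                             effectSize = 3, seed = 1L,
                             nInformative = 10L) {
  if (nComplexes < 10L)
    .err("ppiConfigError", "need at least 10 complexes (got %d)",
         nComplexes)
  feats <- featureNames()
  .withSeed(seed, {
    labels <- sample(rep_len(c("active", "decoy"), nComplexes))
    rows <- list()
    for (cx in seq_len(nComplexes)) {
      isActive <- labels[cx] == "active"
      b <- stats::rnorm(base::length(feats), 0, 0.5)  # complex effect
      for (m in seq_len(modelsPerComplex)) {
        v <- b + stats::rnorm(base::length(feats), 0, sqrt(0.75))
        if (isActive)
          v[seq_len(nInformative)] <- v[seq_len(nInformative)] + effectSize
        row <- as.data.frame(as.list(stats::setNames(v, feats)))
        row <- cbind(data.frame(complex_id = sprintf("cx%03d", cx),
                                model_rank = m, label = labels[cx],
                                stringsAsFactors = FALSE), row)
        rows[[base::length(rows) + 1L]] <- row
      }
    }
    FeatureTable(do.call(rbind, rows))
  })
}

#' Generate a full synthetic screening set
#'
#' Structure+confidence fixtures for an end-to-end screen: active
#' complexes are docked poses with confident-interface bundles; decoys are
#' split between compelling ones (docked pose, uncertain confidence) and
#' separated no-contact pairs.
#'
#' @param nActive,nDecoy complex counts.
#' @param modelsPerComplex models per complex (default 5).
#' @param chainLength residues per chain.
#' @param seed integer seed.
#' @return list of entries: `complex_id`, `label`, `models` (list of
#'   `list(model, conf)`).
#' @export
makeScreeningSet <- function(nActive, nDecoy, modelsPerComplex = 5L,
                             chainLength = 30L, seed = 1L) {
  entries <- list()
  mk <- function(k, label) {
    base <- seed + 1000L * k + (label == "decoy") * 500000L
    ssA <- if (k %% 2L == 0L) "H" else "E"
    chA <- makeChain(chainLength, ssA, seed = base + 1L, id = "A")
    chB <- makeChain(chainLength, "H", seed = base + 2L, id = "B")
    compelling <- label == "decoy" && (k %% 2L == 0L)
    models <- list()
    for (m in seq_len(modelsPerComplex)) {
      mode <- if (label == "active" || compelling) "docked" else "separated"
      mod <- makeComplex(chA, chB, mode, seed = base + 10L + m,
                         complexId = sprintf("%s%03d", substr(label, 1, 1), k),
                         modelRank = m)
      scen <- if (label == "active") "confident_interface"
              else "uncertain_interface"
      conf <- makeConfidence(mod, scen, noiseSd = 1,
                             seed = base + 100L + m)
      models[[m]] <- list(model = mod, conf = conf)
    }
    list(complex_id = sprintf("%s%03d", substr(label, 1, 1), k),
         label = label, models = models)
  }
  for (k in seq_len(nActive))
    entries[[base::length(entries) + 1L]] <- mk(k, "active")
  for (k in seq_len(nDecoy))
    entries[[base::length(entries) + 1L]] <- mk(k, "decoy")
  entries
}

#' Feature table from a screening set
#'
#' @param entries output of [makeScreeningSet()] (or entries of the same
#'   shape).
#' @return a [FeatureTable-class].
#' @export
featureTableFromSet <- function(entries) {
  rows <- lapply(entries, function(e) {
    do.call(rbind, lapply(e$models, function(m) {
      v <- extractFeatures(m$model, m$conf)
      cbind(data.frame(complex_id = e$complex_id,
                       model_rank = modelRank(m$model),
                       label = e$label, stringsAsFactors = FALSE),
            as.data.frame(as.list(v)))
    }))
  })
  FeatureTable(do.call(rbind, rows))
}
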