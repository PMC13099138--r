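# Interface energy features: self-contained analogs of the classic
# molecular-mechanics terms (Lennard-Jones attractive/repulsive split,
# Lazaridis-Karplus-style occlusion solvation, Coulomb with distance-
# dependent dielectric, Kabsch-Sander backbone hydrogen bonds), evaluated
# heavy-atom-only and cross-entity-only.

# Element-class parameter table. sigma is the pair-distance at the LJ
# minimum for a like pair (A); eps in kcal/mol; dgfree/lambda/volume drive
# the solvation occlusion term (positive dgfree = hydrophobic, burial
# favorable).
.ENERGY_PARAMS <- data.frame(
  element = c("C", "N", "O", "S"),
  sigma = c(4.00, 3.65, 3.40, 3.85),
  eps = c(0.105, 0.170, 0.210, 0.250),
  dgfree = c(0.80, -3.20, -2.90, 0.50),
  lambda = c(3.5, 3.5, 3.5, 3.5),
  volume = c(14.7, 11.2, 10.8, 14.7),
  stringsAsFactors = FALSE)

# Fixed cutoffs and switching windows (deterministic evaluation).
.E_CUTOFF_LJ <- 6.0
.E_CUTOFF_SOLV <- 6.0
.E_CUTOFF_ELEC <- 10.0
.E_SWITCH <- 0.5

# Partial charges (e): backbone amide dipole plus ionizable side chains
# (Asp/Glu carboxylates -0.5 per oxygen, Lys NZ +1, Arg guanidinium
# distributed to +1 total). Histidine neutral; termini uncharged.
.SIDECHAIN_CHARGES <- list(
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1.0),
  ARG = c(CZ = 0.2, NH1 = 0.4, NH2 = 0.4))
.BACKBONE_CHARGES <- c(C = 0.51, O = -0.51, N = -0.30)

#' Energy model parameters
#'
#' @return list with the element-class table (`sigma`, `eps` for
#'   Lennard-Jones; `dgfree`, `lambda`, `volume` for solvation), the charge
#'   assignments, and the cutoffs (LJ/solvation 6 A with a 0.5 A linear
#'   switch, electrostatics hard cutoff at 10 A).
#' @export
energyParams <- function() {
  list(classes = .ENERGY_PARAMS,
       backboneCharges = .BACKBONE_CHARGES,
       sidechainCharges = .SIDECHAIN_CHARGES,
       cutoffs = c(lj = .E_CUTOFF_LJ, solv = .E_CUTOFF_SOLV,
                   elec = .E_CUTOFF_ELEC, switch = .E_SWITCH))
}

.ljSwitch <- function(d, cutoff = .E_CUTOFF_LJ, w = .E_SWITCH) {
  s <- rep(1, length(d))
  ramp <- d > (cutoff - w) & d < cutoff
  s[ramp] <- (cutoff - d[ramp]) / w
  s[d >= cutoff] <- 0
  s
}

#' Split Lennard-Jones pair energy
#'
#' LJ(d) = eps * ((sigma/d)^12 - 2 (sigma/d)^6), with minimum -eps at
#' d = sigma. The attractive component is LJ(d) for d >= sigma and is held
#' at -eps inside the minimum; the repulsive component is LJ(d) + eps for
#' d < sigma and 0 otherwise. Both vanish beyond the 6 A cutoff with a
#' linear switch over the last 0.5 A.
#'
#' @param d pair distance(s) in Angstrom (> 0).
#' @param sigma,eps combined pair parameters.
#' @return list with numeric vectors `attractive` (<= 0) and
#'   `repulsive` (>= 0).
#' @export
pairLJ <- function(d, sigma, eps) {
  if (any(d <= 0))
    .err("ppiGeometryError", "non-positive pair distance")
  sr6 <- (sigma / d)^6
  lj <- eps * (sr6^2 - 2 * sr6)
  inside <- d < sigma
  atr <- ifelse(inside, -eps, lj) * .ljSwitch(d)
  rep_ <- ifelse(inside, lj + eps, 0)
  list(attractive = atr, repulsive = rep_)
}

#' Coulomb pair energy with distance-dependent dielectric
#'
#' 332 * qi * qj / (eps(d) * d) with eps(d) = d, i.e. 332 qi qj / d^2,
#' zero at and beyond 10 A.
#'
#' @param d pair distance(s) in Angstrom (> 0).
#' @param qi,qj partial charges (e).
#' @return energy in kcal/mol.
#' @export
#' @examples
#' pairElec(4, 1, -1)  # 332 * (-1) / 16 = -20.75
pairElec <- function(d, qi, qj) {
  if (any(d <= 0))
    .err("ppiGeometryError", "non-positive pair distance")
  e <- 332 * qi * qj / d^2
  e[d >= .E_CUTOFF_ELEC] <- 0
  e
}

.atomParams <- function(atoms) {
  m <- match(atoms$element, .ENERGY_PARAMS$element)
  # unparameterized heavy elements fall back to carbon-like behavior
  m[is.na(m)] <- 1L
  p <- .ENERGY_PARAMS[m, , drop = FALSE]
  q <- unname(.BACKBONE_CHARGES[atoms$elety])
  q[is.na(q)] <- 0
  for (res in names(.SIDECHAIN_CHARGES)) {
    tab <- .SIDECHAIN_CHARGES[[res]]
    hit <- atoms$resid == res & atoms$elety %in% names(tab)
    q[hit] <- unname(tab[atoms$elety[hit]])
  }
  # backbone carbonyl charge must not apply to e.g. side-chain CB ("C" is
  # the exact backbone carbonyl name, so the match above is already exact)
  data.frame(sigma = p$sigma, eps = p$eps, dgfree = p$dgfree,
             lambda = p$lambda, volume = p$volume, charge = q)
}

# Gaussian occlusion desolvation of atom i by occluding atom j at
# distance d: -dgfree_i * V_j / (2 pi^1.5 lambda_i d^2) * exp(-x^2),
# x = (d - r_i) / lambda_i, r_i = sigma_i / 2.
.solvPair <- function(d, pi_, pj) {
  x <- (d - pi_$sigma / 2) / pi_$lambda
  e <- -pi_$dgfree * pj$volume / (2 * pi^1.5 * pi_$lambda * d^2) *
    exp(-x^2)
  e * .ljSwitch(d, .E_CUTOFF_SOLV)
}

#' Solvation (occlusion) score of one residue
#'
#' Sum of Gaussian occlusion terms of the residue's heavy atoms by all
#' heavy atoms of the other entity within the 6 A cutoff. Hydrophobic
#' atoms give favorable (negative) burial terms, polar atoms unfavorable
#' (positive) ones; an isolated residue scores 0.
#'
#' @param model a [ComplexModel-class].
#' @param residueIdx positional residue index.
#' @return energy in kcal/mol.
#' @export
residueSolvation <- function(model, residueIdx) {
  .residueCrossEnergies(model, residueIdx)[["solv"]]
}

# Per-residue cross-entity energy terms (atr, rep, solv, elec) for one
# residue against all atoms of the other entity.
.residueCrossEnergies <- function(model, residueIdx, prm = NULL,
                                  otherAtoms = NULL, otherPrm = NULL) {
  a <- model@atoms
  if (is.null(prm)) prm <- .atomParams(a)
  mine <- which(a$resIdx == residueIdx)
  myEnt <- model@residues$entity[residueIdx]
  if (is.null(otherAtoms)) {
    otherRes <- model@residues$idx[model@residues$entity != myEnt]
    other <- which(a$resIdx %in% otherRes)
    otherAtoms <- a[other, , drop = FALSE]
    otherPrm <- prm[other, , drop = FALSE]
  }
  myAtoms <- a[mine, , drop = FALSE]
  myPrm <- prm[mine, , drop = FALSE]
  .crossEnergyTerms(myAtoms, myPrm, otherAtoms, otherPrm)
}

.crossEnergyTerms <- function(atomsA, prmA, atomsB, prmB) {
  out <- c(atr = 0, rep = 0, solv = 0, elec = 0)
  if (!nrow(atomsA) || !nrow(atomsB)) return(out)
  D <- sqrt(.cdist2(as.matrix(atomsA[, c("x", "y", "z")]),
                    as.matrix(atomsB[, c("x", "y", "z")])))
  near <- which(D < .E_CUTOFF_ELEC, arr.ind = TRUE)
  if (!nrow(near)) return(out)
  ia <- near[, 1L]; ib <- near[, 2L]
  d <- D[near]
  d[d < 0.1] <- 0.1  # numeric floor for pathological overlaps
  sig <- (prmA$sigma[ia] + prmB$sigma[ib]) / 2
  eps <- sqrt(prmA$eps[ia] * prmB$eps[ib])
  lj <- pairLJ(d, sig, eps)
  out["atr"] <- sum(lj$attractive)
  out["rep"] <- sum(lj$repulsive)
  qq <- prmA$charge[ia] * prmB$charge[ib]
  nz <- qq != 0
  if (any(nz)) out["elec"] <- sum(pairElec(d[nz], 1, 1) * qq[nz])
  inSolv <- d < .E_CUTOFF_SOLV
  if (any(inSolv))
    out["solv"] <- sum(.solvPair(d[inSolv],
                                 prmA[ia[inSolv], , drop = FALSE],
                                 prmB[ib[inSolv], , drop = FALSE]))
  out
}

# Cross-entity Kabsch-Sander H-bond energy assigned to interface residues:
# each cross-entity bond's energy (E < -0.5) is credited to both partner
# residues (halved), so per-residue sums aggregate consistently.
.crossHbondPerResidue <- function(model) {
  n <- nResidues(model)
  ent <- .entityVec(model)
  E <- .hbondMatrix(model, energies = TRUE)
  out <- numeric(n)
  cross <- which(E < -0.5, arr.ind = TRUE)
  if (nrow(cross)) {
    keep <- ent[cross[, 1L]] != ent[cross[, 2L]]
    cross <- cross[keep, , drop = FALSE]
    for (k in seq_len(nrow(cross))) {
      e <- E[cross[k, 1L], cross[k, 2L]]
      out[cross[k, 1L]] <- out[cross[k, 1L]] + e / 2
      out[cross[k, 2L]] <- out[cross[k, 2L]] + e / 2
    }
  }
  out
}

# Composite weights for the weighted-total feature.
.ENERGY_WEIGHTS <- c(atr = 1, rep = 0.55, solv = 1, elec = 1, hbond = 1)

#' Interface energy feature block
#'
#' The 17 energy features: per-interfacial-residue cross-entity sums of the
#' attractive/repulsive Lennard-Jones, solvation, electrostatic and
#' hydrogen-bond terms, aggregated as totals and per-interface-residue
#' means, a weighted composite (total and mean), and per-contact-pair
#' means. Empty interfaces give all terms 0.
#'
#' @param model a [ComplexModel-class].
#' @param iface an [InterfaceMap-class] from the same model.
#' @return named numeric vector of the 17 features, manifest order.
#' @export
energyFeatureBlock <- function(model, iface) {
  un <- c(iface@ifaceSet1, iface@ifaceSet2)
  nm <- c("total_lj_atr", "avg_lj_atr", "total_lj_rep", "avg_lj_rep",
          "total_solv", "avg_solv", "total_elec", "avg_elec",
          "total_hbond", "avg_hbond", "total_weighted", "avg_weighted",
          "atr_per_contact_pair", "rep_per_contact_pair",
          "solv_per_contact_pair", "elec_per_contact_pair",
          "hbond_per_contact_pair")
  if (!length(un))
    return(stats::setNames(numeric(length(nm)), nm))
  a <- model@atoms
  prm <- .atomParams(a)
  ent <- .entityVec(model)
  hb <- .crossHbondPerResidue(model)
  terms <- matrix(0, length(un), 5L,
                  dimnames = list(NULL, c("atr", "rep", "solv", "elec",
                                          "hbond")))
  otherCache <- list()
  for (k in seq_along(un)) {
    ri <- un[k]
    e <- ent[ri]
    keyE <- as.character(e)
    if (is.null(otherCache[[keyE]])) {
      rows <- which(ent[a$resIdx] != e)
      otherCache[[keyE]] <- list(atoms = a[rows, , drop = FALSE],
                                 prm = prm[rows, , drop = FALSE])
    }
    oc <- otherCache[[keyE]]
    terms[k, 1:4] <- .residueCrossEnergies(model, ri, prm,
                                           oc$atoms, oc$prm)
    terms[k, "hbond"] <- hb[ri]
  }
  tot <- colSums(terms)
  nIf <- length(un)
  nPairs <- nrow(iface@pairs)
  wTot <- sum(tot * .ENERGY_WEIGHTS[colnames(terms)])
  perPair <- function(x) if (nPairs) x / nPairs else 0
  stats::setNames(
    c(tot["atr"], tot["atr"] / nIf, tot["rep"], tot["rep"] / nIf,
      tot["solv"], tot["solv"] / nIf, tot["elec"], tot["elec"] / nIf,
      tot["hbond"], tot["hbond"] / nIf, wTot, wTot / nIf,
      perPair(tot["atr"]), perPair(tot["rep"]), perPair(tot["solv"]),
      perPair(tot["elec"]), perPair(tot["hbond"])),
    nm)
}
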