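# Internal geometry and error helpers.

# Classed conditions so callers (and the command-line wrapper) can
# distinguish configuration, data, and computation failures.
.err <- function(class, msg, ...) {
  stop(structure(class = c(class, "ppiError", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) .err("ppiGeometryError", "degenerate zero-length vector")
  v / n
}

# Natural-extension-of-reference-frame placement: position atom D given
# three predecessors A-B-C, the C-D bond length, B-C-D angle (deg) and
# A-B-C-D torsion (deg).
.placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Squared-distance matrix between two point sets (rows are points).
.cdist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Kabsch core: returns list(R, t, rmsd) with transform x %*% R + t mapping
# mobile B onto reference A (row-vector convention).
.kabschCore <- function(A, B) {
  cA <- colMeans(A)
  cB <- colMeans(B)
  A0 <- sweep(A, 2L, cA)
  B0 <- sweep(B, 2L, cB)
  H <- crossprod(B0, A0)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  Bt <- B0 %*% R
  rmsd <- sqrt(mean(rowSums((Bt - A0)^2)))
  list(R = R, t = cA - cB %*% R, rmsd = rmsd, singular = sv$d)
}

.applyTransform <- function(X, R, t) {
  sweep(X %*% R, 2L, as.numeric(t), "+")
}

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.AA1TO3 <- structure(names(.AA3TO1), names = unname(.AA3TO1))

.aa321 <- function(resid3) {
  out <- unname(.AA3TO1[toupper(resid3)])
  out[is.na(out)] <- "X"
  out
}

.aa123 <- function(aa1) {
  out <- unname(.AA1TO3[toupper(aa1)])
  out[is.na(out)] <- "UNK"
  out
}

# Representative-atom coordinates for every residue of a ComplexModel:
# C-beta, C-alpha for glycine, C-alpha fallback (with warning) when C-beta
# is absent on a non-glycine residue.
.repCoords <- function(model, warn = TRUE) {
  a <- model@atoms
  r <- model@residues
  n <- nrow(r)
  out <- matrix(NA_real_, n, 3L)
  resIdx <- a$resIdx
  isCB <- a$elety == "CB"
  isCA <- a$elety == "CA"
  cb <- match(seq_len(n), resIdx[isCB])
  ca <- match(seq_len(n), resIdx[isCA])
  cbRows <- which(isCB)[cb]
  caRows <- which(isCA)[ca]
  useCB <- !is.na(cbRows) & r$aa != "G"
  rows <- ifelse(useCB, cbRows, caRows)
  if (anyNA(rows)) {
    bad <- which(is.na(rows))[1L]
    .err("ppiGeometryError",
         "residue %s%d has neither C-beta nor C-alpha", r$chain[bad],
         r$resno[bad])
  }
  fellBack <- !useCB & r$aa != "G"
  if (warn && any(fellBack))
    warning(sprintf("%d non-glycine residue(s) lack C-beta; using C-alpha",
                    sum(fellBack)), call. = FALSE)
  out[] <- as.matrix(a[rows, c("x", "y", "z")])
  out
}

# Backbone coordinate lookup: named list of N x 3 matrices (NA rows where
# an atom is absent) for atoms N, CA, C, O.
.backboneCoords <- function(model) {
  a <- model@atoms
  n <- nrow(model@residues)
  out <- list()
  for (at in c("N", "CA", "C", "O")) {
    m <- matrix(NA_real_, n, 3L)
    sel <- a$elety == at
    rows <- which(sel)[match(seq_len(n), a$resIdx[sel])]
    ok <- !is.na(rows)
    m[ok, ] <- as.matrix(a[rows[ok], c("x", "y", "z")])
    out[[at]] <- m
  }
  out
}

.entityVec <- function(model) model@residues$entity
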