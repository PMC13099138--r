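# Structure and confidence-file input/output; entity grouping.

.normalizeAtomTable <- function(atoms) {
  atoms$ins[is.na(atoms$ins)] <- ""
  atoms$chain <- as.character(atoms$chain)
  atoms$elety <- trimws(atoms$elety)
  # order: chain by first appearance, then author resno, insertion codes
  # after their base residue, then original atom order
  chainOrd <- match(atoms$chain, unique(atoms$chain))
  o <- order(chainOrd, atoms$resno, atoms$ins, seq_len(nrow(atoms)))
  atoms <- atoms[o, , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

.residueTableFromAtoms <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(idx = seq_len(sum(first)),
                    chain = atoms$chain[first],
                    resno = atoms$resno[first],
                    ins = atoms$ins[first],
                    aa = .aa321(atoms$resid[first]),
                    stringsAsFactors = FALSE)
  attr(res, "atomResIdx") <- match(key, key[first])
  res
}

#' Construct a ComplexModel from an atom table
#'
#' @param atoms data.frame with columns chain, resno, ins, resid, elety,
#'   element, x, y, z, b.
#' @param complexId complex identifier.
#' @param modelRank model rank in 1..5.
#' @param entitySpec named integer vector chain -> entity (1 or 2). Default:
#'   first chain is entity 1, all remaining chains entity 2.
#' @return a [ComplexModel-class].
#' @export
ComplexModel <- function(atoms, complexId = "complex", modelRank = 1L,
                         entitySpec = NULL) {
  msg <- .checkAtomTable(atoms)
  if (!is.null(msg)) .err("ppiParseError", "%s", msg)
  atoms <- .normalizeAtomTable(atoms)
  res <- .residueTableFromAtoms(atoms)
  atoms$resIdx <- attr(res, "atomResIdx")
  chains <- unique(res$chain)
  if (length(chains) < 2L)
    .err("ppiStructuralError",
         "a complex model requires at least 2 chains (found %d)",
         length(chains))
  if (is.null(entitySpec)) {
    entitySpec <- c(1L, rep(2L, length(chains) - 1L))
    names(entitySpec) <- chains
  }
  entitySpec <- .checkEntitySpec(entitySpec, chains)
  res$entity <- unname(entitySpec[res$chain])
  attr(res, "atomResIdx") <- NULL
  new("ComplexModel", complexId = as.character(complexId),
      modelRank = as.integer(modelRank), atoms = atoms, residues = res,
      entityOfChain = entitySpec)
}

.checkEntitySpec <- function(spec, chains) {
  spec <- vapply(spec, as.integer, 1L)
  missing <- setdiff(chains, names(spec))
  if (length(missing))
    .err("ppiSpecError", "entity spec missing chain(s): %s",
         paste(missing, collapse = ", "))
  spec <- spec[chains]
  if (!all(spec %in% c(1L, 2L)))
    .err("ppiSpecError", "entity labels must be 1 or 2")
  if (length(unique(spec)) != 2L)
    .err("ppiSpecError", "both entities must contain at least one chain")
  spec
}

#' Read a predicted complex structure
#'
#' Parses a PDB or mmCIF file (via bio3d), keeps heavy protein atoms,
#' resolves altlocs to the highest-occupancy conformer, and orders residues
#' by chain then author numbering with insertion codes after their base
#' residue.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @param complexId,modelRank identifiers attached to the model.
#' @param entitySpec optional named chain -> entity map (see
#'   [ComplexModel()]).
#' @return a [ComplexModel-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          complexId = NULL, modelRank = 1L,
                          entitySpec = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    .err("ppiParseError", "file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e)
      .err("ppiParseError", "failed to parse %s as %s: %s", path, format,
           conditionMessage(e)))
  a <- parsed$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (!nrow(a))
    .err("ppiParseError", "no ATOM records in %s", path)
  # heavy atoms only
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy)))
    elesy <- substr(gsub("[0-9]", "", a$elety), 1L, 1L)
  a <- a[toupper(trimws(elesy)) != "H", , drop = FALSE]
  # altloc: keep highest-occupancy conformer, ties to first altloc code
  occ <- a$o
  occ[is.na(occ)] <- 1
  alt <- a$alt
  alt[is.na(alt)] <- ""
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  fileOrder <- seq_len(nrow(a))
  o <- order(key, -occ, alt)
  a <- a[o, , drop = FALSE]
  keep <- !duplicated(paste(a$chain, a$resno, a$insert, a$elety,
                            sep = "\r"))
  a <- a[keep, , drop = FALSE]
  a <- a[order(fileOrder[o][keep]), , drop = FALSE]  # restore file order
  elem <- toupper(trimws(a$elesy))
  if (is.null(a$elesy) || all(!nzchar(elem)))
    elem <- substr(gsub("[0-9]", "", a$elety), 1L, 1L)
  atoms <- data.frame(chain = as.character(a$chain), resno = a$resno,
                      ins = ifelse(is.na(a$insert), "", a$insert),
                      resid = a$resid, elety = a$elety, element = elem,
                      x = a$x, y = a$y, z = a$z,
                      b = ifelse(is.na(a$b), 0, a$b),
                      stringsAsFactors = FALSE)
  # drop residues with no C-alpha (ligand fragments etc.)
  rkey <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  hasCA <- rkey %in% rkey[atoms$elety == "CA"]
  if (any(!hasCA)) {
    warning(sprintf("dropping %d residue(s) without C-alpha in %s",
                    length(unique(rkey[!hasCA])), basename(path)),
            call. = FALSE)
    atoms <- atoms[hasCA, , drop = FALSE]
  }
  if (is.null(complexId))
    complexId <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                     ignore.case = TRUE)
  ComplexModel(atoms, complexId = complexId, modelRank = modelRank,
               entitySpec = entitySpec)
}

#' Write a model (or single chain) as PDB
#'
#' @param object a [ComplexModel-class] or [ProteinStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(object, path) {
  a <- if (is(object, "ComplexModel")) object@atoms else object@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), resno = a$resno,
                   resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(nzchar(a$ins), a$ins, NA),
                   o = rep(1, nrow(a)), b = a$b, elesy = a$element)
  invisible(path)
}

#' Write a model as a minimal mmCIF file
#'
#' Emits a single `atom_site` loop (the subset of the mmCIF scheme needed
#' to round-trip the heavy-atom inventory); used to produce mmCIF fixtures
#' mirroring the PDB writer.
#'
#' @param object a [ComplexModel-class] or [ProteinStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructureCif <- function(object, path) {
  a <- object@atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_model", "#", "loop_",
               paste0("_atom_site.",
                      c("group_PDB", "id", "type_symbol", "label_atom_id",
                        "label_alt_id", "label_comp_id", "label_asym_id",
                        "label_entity_id", "label_seq_id",
                        "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                        "Cartn_z", "occupancy", "B_iso_or_equiv",
                        "auth_seq_id", "auth_comp_id", "auth_asym_id",
                        "auth_atom_id", "pdbx_PDB_model_num"))), con)
  lines <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 %.2f %d %s %s %s 1",
    seq_len(nrow(a)), a$element, a$elety, a$resid, a$chain, a$resno,
    ifelse(nzchar(a$ins), a$ins, "?"), a$x, a$y, a$z, a$b, a$resno,
    a$resid, a$chain, a$elety)
  writeLines(c(lines, "#"), con)
  invisible(path)
}

#' Construct a confidence bundle
#'
#' Missing pTM/iPTM are imputed as 0 with a warning (older score files omit
#' them).
#'
#' @param plddt per-residue pLDDT in \[0, 100\].
#' @param pae N x N predicted-aligned-error matrix (Angstrom).
#' @param ptm,iptm scalar scores in \[0, 1\] (or NULL/NA to impute 0).
#' @return a [ConfidenceBundle-class].
#' @export
ConfidenceBundle <- function(plddt, pae, ptm = NULL, iptm = NULL) {
  fix <- function(v, name) {
    if (is.null(v) || !length(v) || is.na(v)) {
      warning(sprintf("%s missing; imputed as 0", name), call. = FALSE)
      0
    } else as.numeric(v)
  }
  pae <- as.matrix(pae)
  obj <- new("ConfidenceBundle", plddt = as.numeric(plddt), pae = pae,
             ptm = fix(ptm, "ptm"), iptm = fix(iptm, "iptm"))
  obj
}

.CONF_KEYS <- list(plddt = c("plddt", "pLDDT", "plddts"),
                   pae = c("pae", "predicted_aligned_error"),
                   ptm = c("ptm", "pTM"),
                   iptm = c("iptm", "ipTM"))

#' Read a model confidence file
#'
#' Reads the JSON dialect with keys `plddt` (flat list), `pae` (list of
#' lists), `ptm`, `iptm`; the common predicted-model score-file variants
#' (`pLDDT`/`predicted_aligned_error`/`ipTM`) are mapped onto it.
#'
#' @param path JSON file path.
#' @param expectedN residue count of the paired model; the PAE matrix must
#'   be `expectedN x expectedN`.
#' @return a [ConfidenceBundle-class].
#' @export
readConfidence <- function(path, expectedN) {
  if (!file.exists(path))
    .err("ppiDialectError", "confidence file not found: %s", path)
  js <- tryCatch(jsonlite::fromJSON(path),
                 error = function(e)
                   .err("ppiDialectError", "failed to parse JSON %s: %s",
                        path, conditionMessage(e)))
  pick <- function(field, required = TRUE) {
    for (k in .CONF_KEYS[[field]]) if (!is.null(js[[k]])) return(js[[k]])
    if (required)
      .err("ppiDialectError", "confidence file %s lacks key '%s'", path,
           field)
    NULL
  }
  plddt <- as.numeric(pick("plddt"))
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100))
    .err("ppiValidationError", "pLDDT values outside [0, 100] in %s", path)
  paeRaw <- pick("pae")
  paeM <- if (is.matrix(paeRaw)) paeRaw else do.call(rbind, paeRaw)
  if (!is.matrix(paeM) || nrow(paeM) != ncol(paeM))
    .err("ppiPairingError", "PAE matrix in %s is not square (%d x %d)",
         path, NROW(paeM), NCOL(paeM))
  if (nrow(paeM) != expectedN || length(plddt) != expectedN)
    .err("ppiPairingError",
         "confidence dimension mismatch in %s: PAE %d, pLDDT %d, expected %d",
         path, nrow(paeM), length(plddt), expectedN)
  ptm <- pick("ptm", required = FALSE)
  iptm <- pick("iptm", required = FALSE)
  ConfidenceBundle(plddt, paeM, ptm, iptm)
}

#' Write a confidence bundle as JSON
#'
#' @param conf a [ConfidenceBundle-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConfidence <- function(conf, path) {
  jsonlite::write_json(list(plddt = conf@plddt,
                            pae = apply(conf@pae, 1L, as.numeric,
                                        simplify = FALSE),
                            ptm = conf@ptm, iptm = conf@iptm),
                       path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' Regroup chains into the two screening entities
#'
#' All downstream "interchain" definitions (interface, PAE statistics,
#' cross energies) operate cross-entity, so e.g. three copies of a trimeric
#' ligand can be grouped as entity 1 against a receptor as entity 2.
#'
#' @param model a [ComplexModel-class].
#' @param spec named vector mapping every chain id to 1 or 2.
#' @return the regrouped [ComplexModel-class] (residue order unchanged).
#' @export
groupEntities <- function(model, spec) {
  chains <- unique(model@residues$chain)
  spec <- .checkEntitySpec(spec, chains)
  model@entityOfChain <- spec
  model@residues$entity <- unname(spec[model@residues$chain])
  validObject(model)
  model
}

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

#' Write sequences as FASTA
#'
#' Standard FASTA with 60-character wrapping, one record per component, in
#' input order; used to hand decoy sequence pairs to an external structure
#' predictor.
#'
#' @param records named character vector (names are record ids) or list of
#'   `c(id, sequence)` pairs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path) {
  if (is.list(records)) {
    ids <- vapply(records, `[[`, "", 1L)
    seqs <- vapply(records, `[[`, "", 2L)
  } else {
    ids <- names(records)
    seqs <- unname(records)
  }
  if (is.null(ids) || any(!nzchar(ids)))
    .err("ppiRecordError", "every FASTA record needs a non-empty id")
  for (k in seq_along(seqs)) {
    if (!nzchar(seqs[k]))
      .err("ppiRecordError", "empty sequence for record '%s'", ids[k])
    letters <- strsplit(seqs[k], "")[[1]]
    bad <- setdiff(unique(letters), .AA_ALPHABET)
    if (length(bad))
      .err("ppiRecordError",
           "record '%s' has non-amino-acid character(s): %s", ids[k],
           paste(bad, collapse = ""))
  }
  aas <- Biostrings::AAStringSet(seqs)
  names(aas) <- ids
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Dataset membership predicate for complex metadata
#'
#' Routes a candidate complex by the training-set filters: drop on
#' resolution > 3 Angstrom, sequence identity > 30%, total length > 1550
#' residues, homodimers and antibody/antigen complexes; route to the
#' protein-peptide branch when the shorter chain is under 50 residues;
#' otherwise keep in the protein-protein set.
#'
#' @param meta list or one-row data.frame with fields `resolution`,
#'   `pct_identity`, `total_len`, `min_chain_len`, `is_homodimer`,
#'   `is_antibody`.
#' @return one of `"keep_protein_protein"`, `"route_peptide"`, `"drop"`.
#' @export
filterComplexMetadata <- function(meta) {
  need <- c("resolution", "pct_identity", "total_len", "min_chain_len",
            "is_homodimer", "is_antibody")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    .err("ppiDataError", "metadata missing field(s): %s",
         paste(miss, collapse = ", "))
  if (meta$resolution > 3 || meta$pct_identity > 30 ||
      meta$total_len > 1550 || isTRUE(meta$is_homodimer) ||
      isTRUE(meta$is_antibody)) return("drop")
  if (meta$min_chain_len < 50) return("route_peptide")
  "keep_protein_protein"
}

#' Construct a single-chain protein structure
#'
#' @param atoms heavy-atom data.frame (see [ComplexModel()]), one chain.
#' @param id identifier.
#' @return a [ProteinStructure-class].
#' @export
ProteinStructure <- function(atoms, id) {
  atoms <- .normalizeAtomTable(atoms)
  new("ProteinStructure", id = as.character(id), atoms = atoms)
}

#' Extract one chain of a model as a ProteinStructure
#'
#' @param model a [ComplexModel-class].
#' @param chain chain identifier.
#' @param id id for the extracted structure (default `complexId_chain`).
#' @return a [ProteinStructure-class].
#' @export
extractChain <- function(model, chain, id = NULL) {
  a <- model@atoms[model@atoms$chain == chain, , drop = FALSE]
  if (!nrow(a))
    .err("ppiStructuralError", "model has no chain '%s'", chain)
  a$resIdx <- NULL
  if (is.null(id)) id <- paste(model@complexId, chain, sep = "_")
  ProteinStructure(a, id)
}

#' C-alpha coordinates of a single-chain structure
#'
#' @param ps a [ProteinStructure-class].
#' @return N x 3 numeric matrix in residue order.
#' @export
caCoords <- function(ps) {
  a <- ps@atoms[ps@atoms$elety == "CA", , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}
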