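#' @import methods
NULL

.ATOM_COLS <- c("chain", "resno", "ins", "resid", "elety", "element",
                "x", "y", "z", "b")

.checkAtomTable <- function(atoms) {
  if (!is.data.frame(atoms)) return("atoms must be a data.frame")
  miss <- setdiff(.ATOM_COLS, names(atoms))
  if (length(miss)) return(paste("atoms table missing columns:",
                                 paste(miss, collapse = ", ")))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(xyz))) return("non-finite coordinates")
  if (nrow(atoms) && any(!nzchar(atoms$elety))) return("empty atom name")
  NULL
}

#' Single-chain protein structure
#'
#' Holds one protein chain as a heavy-atom table. Used as the unit of the
#' decoy-generation library and as the building block for synthetic
#' complexes.
#'
#' @slot id character identifier.
#' @slot atoms data.frame with columns chain, resno, ins, resid (3-letter),
#'   elety (atom name), element, x, y, z, b.
#' @exportClass ProteinStructure
setClass("ProteinStructure",
         representation(id = "character", atoms = "data.frame"),
         validity = function(object) {
           msg <- .checkAtomTable(object@atoms)
           if (!is.null(msg)) return(msg)
           if (length(object@id) != 1L || !nzchar(object@id))
             return("id must be a single non-empty string")
           if (!nrow(object@atoms)) return("structure has no atoms")
           TRUE
         })

#' Predicted complex model partitioned into two screening entities
#'
#' A multi-chain structure whose chains are grouped into exactly two
#' entities; every cross-"chain" definition downstream (interface, PAE
#' statistics, energies) means cross-entity, so a trimeric ligand grouped
#' as entity 1 against its receptor as entity 2 is handled unchanged.
#'
#' @slot complexId character identifier of the protein pairing.
#' @slot modelRank integer model rank (1-5 for a five-model prediction).
#' @slot atoms heavy-atom data.frame (see [ProteinStructure-class]).
#' @slot residues data.frame with one row per residue: idx (positional,
#'   1..N in concatenated chain order), chain, resno, ins, aa (one-letter),
#'   entity (1 or 2).
#' @slot entityOfChain named integer vector mapping chain id to entity.
#' @exportClass ComplexModel
setClass("ComplexModel",
         representation(complexId = "character", modelRank = "integer",
                        atoms = "data.frame", residues = "data.frame",
                        entityOfChain = "integer"),
         validity = function(object) {
           msg <- .checkAtomTable(object@atoms)
           if (!is.null(msg)) return(msg)
           ents <- sort(unique(object@entityOfChain))
           if (!identical(as.integer(ents), c(1L, 2L)))
             return("chains must be partitioned into exactly two entities")
           if (!all(object@residues$entity %in% c(1L, 2L)))
             return("residue entity labels must be 1 or 2")
           for (e in 1:2)
             if (!any(object@residues$entity == e))
               return(sprintf("entity %d has no residues", e))
           if (anyDuplicated(object@residues[, c("chain", "resno", "ins")]))
             return("duplicate (chain, resno, ins) residue identifiers")
           if (!(length(object@modelRank) == 1L &&
                 object@modelRank >= 1L && object@modelRank <= 5L))
             return("modelRank must be a single integer in 1..5")
           TRUE
         })

#' Per-model prediction confidence bundle
#'
#' @slot plddt numeric vector of per-residue pLDDT values in \[0, 100\].
#' @slot pae N x N matrix of predicted aligned error (Angstrom, >= 0).
#' @slot ptm predicted TM-score in \[0, 1\].
#' @slot iptm interface predicted TM-score in \[0, 1\].
#' @exportClass ConfidenceBundle
setClass("ConfidenceBundle",
         representation(plddt = "numeric", pae = "matrix",
                        ptm = "numeric", iptm = "numeric"),
         validity = function(object) {
           n <- length(object@plddt)
           if (any(!is.finite(object@plddt)) ||
               any(object@plddt < 0 | object@plddt > 100))
             return("plddt values must be finite and within [0, 100]")
           if (nrow(object@pae) != ncol(object@pae))
             return("pae matrix must be square")
           if (nrow(object@pae) != n)
             return("pae dimension must equal length(plddt)")
           if (any(!is.finite(object@pae)) || any(object@pae < 0))
             return("pae values must be finite and non-negative")
           for (s in c("ptm", "iptm")) {
             v <- slot(object, s)
             if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
               return(sprintf("%s must be a single value in [0, 1]", s))
           }
           TRUE
         })

#' Cross-entity interface map
#'
#' Residue pairs whose representative atoms (C-beta, C-alpha for glycine)
#' lie within the cutoff, plus the per-entity interface residue sets.
#'
#' @slot pairs integer matrix with columns `i` (entity-1 residue index) and
#'   `j` (entity-2 residue index), positional 1..N indices.
#' @slot ifaceSet1,ifaceSet2 sorted integer vectors of interface residues.
#' @slot cutoff numeric cutoff in Angstrom (default rule: 12).
#' @exportClass InterfaceMap
setClass("InterfaceMap",
         representation(pairs = "matrix", ifaceSet1 = "integer",
                        ifaceSet2 = "integer", cutoff = "numeric"),
         validity = function(object) {
           p <- object@pairs
           if (ncol(p) != 2L) return("pairs must have two columns")
           if (!setequal(object@ifaceSet1, unique(p[, 1L])) ||
               !setequal(object@ifaceSet2, unique(p[, 2L])))
             return("interface sets must be the projections of pairs")
           if (object@cutoff <= 0) return("cutoff must be positive")
           TRUE
         })

#' Rigid-body superposition result
#'
#' Least-squares (Kabsch) transform mapping a mobile coordinate set onto a
#' reference: `transformed = mobile %*% rotation + translation` (row
#' vectors).
#'
#' @slot rotation 3x3 proper rotation matrix (det +1).
#' @slot translation length-3 numeric vector (Angstrom).
#' @slot rmsd root-mean-square deviation after superposition (Angstrom).
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
         representation(rotation = "matrix", translation = "numeric",
                        rmsd = "numeric"),
         validity = function(object) {
           R <- object@rotation
           if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
           if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det +1)")
           if (max(abs(crossprod(R) - diag(3))) > 1e-6)
             return("rotation must be orthonormal")
           if (object@rmsd < -1e-9) return("rmsd must be non-negative")
           TRUE
         })

#' Labeled per-model feature table
#'
#' Rows are (complex_id, model_rank, label) plus the manifest-ordered
#' feature columns.
#'
#' @slot data data.frame with id columns `complex_id`, `model_rank`,
#'   `label` followed by the feature columns in manifest order.
#' @slot manifestVersion character manifest version tag.
#' @exportClass FeatureTable
setClass("FeatureTable",
         representation(data = "data.frame", manifestVersion = "character"),
         validity = function(object) {
           d <- object@data
           idc <- c("complex_id", "model_rank", "label")
           if (!all(idc %in% names(d)))
             return("data must carry complex_id, model_rank, label columns")
           if (nrow(d) && !all(d$label %in% c("active", "decoy")))
             return("label must be 'active' or 'decoy'")
           feat <- setdiff(names(d), idc)
           if (nrow(d) && any(vapply(d[feat], function(x) any(is.na(x)), TRUE)))
             return("feature columns must have no missing values")
           tab <- table(d$complex_id)
           if (length(tab) && max(tab) > 5L)
             return("at most 5 rows (models) per complex_id")
           TRUE
         })

#' Grouped split assignment
#'
#' Complex-level assignment to train/validation/test; all models of one
#' complex share an assignment (leakage guard).
#'
#' @slot assignment data.frame with columns complex_id, split.
#' @slot fractions named numeric fractions (train, validation, test).
#' @slot seed integer seed used for the draw.
#' @exportClass SplitAssignment
setClass("SplitAssignment",
         representation(assignment = "data.frame", fractions = "numeric",
                        seed = "integer"),
         validity = function(object) {
           a <- object@assignment
           if (!all(c("complex_id", "split") %in% names(a)))
             return("assignment needs complex_id and split columns")
           if (!all(a$split %in% c("train", "validation", "test")))
             return("split must be train/validation/test")
           if (anyDuplicated(a$complex_id))
             return("each complex_id must have exactly one assignment")
           TRUE
         })

#' Trained interaction classifier
#'
#' @slot fit fitted classifier object (gradient-boosted ensemble or glm).
#' @slot type character, "xgboost" or "logistic".
#' @slot features ordered character vector of feature names used.
#' @slot hyperparams named list of hyperparameters.
#' @slot thresholds threshold-performance data.frame (may be empty).
#' @slot metadata list (seed, folds, manifest version, cv AUC).
#' @exportClass TrainedModel
setClass("TrainedModel",
         representation(fit = "ANY", type = "character",
                        features = "character", hyperparams = "list",
                        thresholds = "data.frame", metadata = "list"),
         validity = function(object) {
           if (!object@type %in% c("xgboost", "logistic"))
             return("type must be 'xgboost' or 'logistic'")
           if (!length(object@features)) return("empty feature subset")
           TRUE
         })

#' Decoy construction recipe
#'
#' @slot templateComplexId id of the active complex used as template.
#' @slot analogId1,analogId2 ids of the structural analogs placed.
#' @slot tmScore1,tmScore2 TM-scores of analog to replaced component.
#' @slot rankUsed1,rankUsed2 "best" or "second_best".
#' @slot transforms list of two [SuperpositionResult-class] objects.
#' @exportClass DecoyRecipe
setClass("DecoyRecipe",
         representation(templateComplexId = "character",
                        analogId1 = "character", analogId2 = "character",
                        tmScore1 = "numeric", tmScore2 = "numeric",
                        rankUsed1 = "character", rankUsed2 = "character",
                        transforms = "list"),
         validity = function(object) {
           if (!all(c(object@rankUsed1, object@rankUsed2) %in%
                    c("best", "second_best")))
             return("rankUsed must be 'best' or 'second_best'")
           ok <- function(v) length(v) == 1L && v > 0 && v <= 1 + 1e-9
           if (!ok(object@tmScore1) || !ok(object@tmScore2))
             return("TM-scores must lie in (0, 1]")
           TRUE
         })

#' Family selectivity grid
#'
#' Complete ligand x receptor score matrix from an all-vs-all screen,
#' optionally with a known-interaction mask.
#'
#' @slot scores numeric matrix, rows = ligands, cols = receptors, in \[0,1\].
#' @slot knownMask logical matrix of the same shape, or 0x0 if absent.
#' @exportClass SelectivityGrid
setClass("SelectivityGrid",
         representation(scores = "matrix", knownMask = "matrix"),
         validity = function(object) {
           s <- object@scores
           if (is.null(rownames(s)) || is.null(colnames(s)))
             return("scores must carry ligand rownames and receptor colnames")
           if (any(!is.finite(s)) || any(s < -1e-9 | s > 1 + 1e-9))
             return("scores must be complete and within [0, 1]")
           m <- object@knownMask
           if (length(m) && !identical(dim(m), dim(s)))
             return("knownMask must match the score matrix shape")
           TRUE
         })

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf("ProteinStructure '%s': %d residues, %d atoms\n", object@id,
              length(unique(paste(object@atoms$chain, object@atoms$resno,
                                  object@atoms$ins))),
              nrow(object@atoms)))
})

setMethod("show", "ComplexModel", function(object) {
  r <- object@residues
  cat(sprintf("ComplexModel '%s' (rank %d): %d residues, %d atoms\n",
              object@complexId, object@modelRank, nrow(r),
              nrow(object@atoms)))
  for (e in 1:2) {
    ch <- names(object@entityOfChain)[object@entityOfChain == e]
    cat(sprintf("  entity %d: chains %s (%d residues)\n", e,
                paste(ch, collapse = ","), sum(r$entity == e)))
  }
})

setMethod("show", "ConfidenceBundle", function(object) {
  cat(sprintf(
    "ConfidenceBundle: N=%d, mean pLDDT %.1f, pTM %.3f, iPTM %.3f\n",
    length(object@plddt), mean(object@plddt), object@ptm, object@iptm))
})

setMethod("show", "InterfaceMap", function(object) {
  cat(sprintf(
    "InterfaceMap (cutoff %.1f A): %d pairs, %d + %d interface residues\n",
    object@cutoff, nrow(object@pairs), length(object@ifaceSet1),
    length(object@ifaceSet2)))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable (manifest %s): %d rows, %d complexes, %d features\n",
              object@manifestVersion, nrow(object@data),
              length(unique(object@data$complex_id)),
              ncol(object@data) - 3L))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel (%s): %d features", object@type,
              length(object@features)))
  if (!is.null(object@metadata$cv_auc))
    cat(sprintf(", cross-fold AUC %.3f", object@metadata$cv_auc))
  cat("\n")
})

setMethod("show", "SelectivityGrid", function(object) {
  cat(sprintf("SelectivityGrid: %d ligands x %d receptors%s\n",
              nrow(object@scores), ncol(object@scores),
              if (length(object@knownMask)) " (with known mask)" else ""))
})
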