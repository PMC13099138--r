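#' Accessors for package classes
#'
#' Standard accessor generics: number of residues, atom and residue tables,
#' entity labels, identifiers.
#'
#' @param object an object of one of the package's classes.
#' @return The requested component (see individual methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nResidues", function(object) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("atomData", function(object) standardGeneric("atomData"))

#' @rdname accessors
#' @export
setGeneric("residueData", function(object) standardGeneric("residueData"))

#' @rdname accessors
#' @export
setGeneric("complexId", function(object) standardGeneric("complexId"))

#' @rdname accessors
#' @export
setGeneric("modelRank", function(object) standardGeneric("modelRank"))

#' @rdname accessors
#' @export
setGeneric("entityOfChain", function(object) standardGeneric("entityOfChain"))

#' @rdname accessors
#' @export
setGeneric("sequenceOf", function(object, ...) standardGeneric("sequenceOf"))

#' @rdname accessors
#' @export
setMethod("nResidues", "ComplexModel",
          function(object) nrow(object@residues))

#' @rdname accessors
#' @export
setMethod("nResidues", "ProteinStructure", function(object) {
  nrow(unique(object@atoms[, c("chain", "resno", "ins")]))
})

#' @rdname accessors
#' @export
setMethod("atomData", "ComplexModel", function(object) object@atoms)

#' @rdname accessors
#' @export
setMethod("atomData", "ProteinStructure", function(object) object@atoms)

#' @rdname accessors
#' @export
setMethod("residueData", "ComplexModel", function(object) object@residues)

#' @rdname accessors
#' @export
setMethod("complexId", "ComplexModel", function(object) object@complexId)

#' @rdname accessors
#' @export
setMethod("modelRank", "ComplexModel", function(object) object@modelRank)

#' @rdname accessors
#' @export
setMethod("entityOfChain", "ComplexModel",
          function(object) object@entityOfChain)

#' @rdname accessors
#' @export
setMethod("sequenceOf", "ComplexModel", function(object, entity = NULL) {
  r <- object@residues
  if (!is.null(entity)) r <- r[r$entity == entity, , drop = FALSE]
  paste(r$aa, collapse = "")
})

#' @rdname accessors
#' @export
setMethod("sequenceOf", "ProteinStructure", function(object) {
  a <- object@atoms
  key <- !duplicated(paste(a$chain, a$resno, a$ins))
  paste(.aa321(a$resid[key]), collapse = "")
})

#' Per-residue pLDDT, PAE matrix and pTM/iPTM accessors
#'
#' @param object a [ConfidenceBundle-class].
#' @return numeric vector / matrix / scalar respectively.
#' @name confidence-accessors
NULL

#' @rdname confidence-accessors
#' @export
setGeneric("plddt", function(object) standardGeneric("plddt"))

#' @rdname confidence-accessors
#' @export
setGeneric("pae", function(object) standardGeneric("pae"))

#' @rdname confidence-accessors
#' @export
setGeneric("ptm", function(object) standardGeneric("ptm"))

#' @rdname confidence-accessors
#' @export
setGeneric("iptm", function(object) standardGeneric("iptm"))

#' @rdname confidence-accessors
#' @export
setMethod("plddt", "ConfidenceBundle", function(object) object@plddt)

#' @rdname confidence-accessors
#' @export
setMethod("pae", "ConfidenceBundle", function(object) object@pae)

#' @rdname confidence-accessors
#' @export
setMethod("ptm", "ConfidenceBundle", function(object) object@ptm)

#' @rdname confidence-accessors
#' @export
setMethod("iptm", "ConfidenceBundle", function(object) object@iptm)

#' Interface map accessors
#'
#' @param object an [InterfaceMap-class].
#' @return integer matrix of pairs, or the per-entity residue index sets.
#' @name interface-accessors
NULL

#' @rdname interface-accessors
#' @export
setGeneric("interfacePairs", function(object) standardGeneric("interfacePairs"))

#' @rdname interface-accessors
#' @export
setGeneric("interfaceResidues",
           function(object, entity) standardGeneric("interfaceResidues"))

#' @rdname interface-accessors
#' @export
setMethod("interfacePairs", "InterfaceMap", function(object) object@pairs)

#' @rdname interface-accessors
#' @export
setMethod("interfaceResidues", "InterfaceMap", function(object, entity) {
  stopifnot(entity %in% c(1L, 2L))
  if (entity == 1L) object@ifaceSet1 else object@ifaceSet2
})

#' Feature table accessors
#'
#' @param object a [FeatureTable-class].
#' @return the underlying data.frame, or the manifest version string.
#' @name featuretable-accessors
NULL

#' @rdname featuretable-accessors
#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))

#' @rdname featuretable-accessors
#' @export
setGeneric("manifestVersion",
           function(object) standardGeneric("manifestVersion"))

#' @rdname featuretable-accessors
#' @export
setMethod("featureData", "FeatureTable", function(object) object@data)

#' @rdname featuretable-accessors
#' @export
setMethod("manifestVersion", "FeatureTable",
          function(object) object@manifestVersion)

#' Selectivity grid accessors
#'
#' @param object a [SelectivityGrid-class].
#' @return the score matrix or the known-interaction mask (NULL if absent).
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridScores", function(object) standardGeneric("gridScores"))

#' @rdname grid-accessors
#' @export
setGeneric("knownMask", function(object) standardGeneric("knownMask"))

#' @rdname grid-accessors
#' @export
setMethod("gridScores", "SelectivityGrid", function(object) object@scores)

#' @rdname grid-accessors
#' @export
setMethod("knownMask", "SelectivityGrid", function(object) {
  if (length(object@knownMask)) object@knownMask else NULL
})
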