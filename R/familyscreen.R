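# All-vs-all ligand/receptor selectivity screening (trimeric-ligand
# families: ligand chains grouped as entity 1, receptor as entity 2).

#' Enumerate all ligand/receptor pairings
#'
#' Full Cartesian product in row-major order (for each ligand, all
#' receptors).
#'
#' @param ligands,receptors character vectors of unique ids.
#' @return data.frame with columns `ligand`, `receptor`.
#' @export
#' @examples
#' nrow(enumeratePairings(paste0("L", 1:18), paste0("R", 1:28)))  # 504
enumeratePairings <- function(ligands, receptors) {
  if (!length(ligands) || !length(receptors))
    .err("ppiIdError", "ligand and receptor lists must be non-empty")
  if (anyDuplicated(ligands) || anyDuplicated(receptors))
    .err("ppiIdError", "duplicate ligand or receptor ids")
  data.frame(ligand = rep(ligands, each = length(receptors)),
             receptor = rep(receptors, times = length(ligands)),
             stringsAsFactors = FALSE)
}

#' Score an all-vs-all selectivity grid
#'
#' Each cell is the maximum classifier score over that pairing's models
#' (five per pairing in a standard screen). Chain grouping (e.g. three
#' ligand copies as entity 1) is applied through each model's entity spec
#' before feature extraction.
#'
#' @param entries list of pairing entries, each a list with `ligand`,
#'   `receptor`, and `models` (a list of `list(model = ComplexModel,
#'   conf = ConfidenceBundle)`); optionally `entitySpec` applied to every
#'   model of the entry.
#' @param trained a [TrainedModel-class].
#' @param ligands,receptors expected grid axes; inferred from entries if
#'   NULL. Missing pairings are an error listing the gaps.
#' @param knownMask optional logical matrix (ligand x receptor).
#' @return a [SelectivityGrid-class].
#' @export
screenGrid <- function(entries, trained, ligands = NULL, receptors = NULL,
                       knownMask = NULL) {
  ls <- vapply(entries, `[[`, "", "ligand")
  rs <- vapply(entries, `[[`, "", "receptor")
  if (is.null(ligands)) ligands <- unique(ls)
  if (is.null(receptors)) receptors <- unique(rs)
  want <- enumeratePairings(ligands, receptors)
  have <- paste(ls, rs)
  gaps <- setdiff(paste(want$ligand, want$receptor), have)
  if (length(gaps))
    .err("ppiGridError", "missing pairing(s): %s",
         paste(utils::head(gaps, 10L), collapse = "; "))
  scores <- matrix(NA_real_, length(ligands), length(receptors),
                   dimnames = list(ligands, receptors))
  for (e in entries) {
    cell <- vapply(e$models, function(m) {
      model <- m$model
      if (!is.null(e$entitySpec)) model <- groupEntities(model, e$entitySpec)
      feats <- extractFeatures(model, m$conf)
      d <- as.data.frame(t(feats))
      as.numeric(.predictClassifier(trained@fit,
                                    as.matrix(d[, trained@features,
                                                drop = FALSE])))
    }, 0)
    scores[e$ligand, e$receptor] <- max(cell)
  }
  new("SelectivityGrid", scores = scores,
      knownMask = if (is.null(knownMask)) matrix(logical(0), 0, 0)
                  else knownMask[ligands, receptors, drop = FALSE])
}

#' Build a selectivity grid from precomputed scores
#'
#' @param scores named numeric matrix (ligands x receptors), complete.
#' @param knownMask optional logical matrix of the same shape.
#' @return a [SelectivityGrid-class].
#' @export
SelectivityGrid <- function(scores, knownMask = NULL) {
  new("SelectivityGrid", scores = scores,
      knownMask = if (is.null(knownMask)) matrix(logical(0), 0, 0)
                  else knownMask)
}

#' Top-k hit report per ligand
#'
#' A ligand is a hit at k if any of its known receptors is among its k
#' top-scoring receptors; score ties are broken by lexicographic receptor
#' id. Ligands with no known receptor are excluded with a warning.
#'
#' @param grid a [SelectivityGrid-class] with a known mask.
#' @param k number of top receptors to consider (default 1).
#' @return list with `hits` (data.frame ligand/hit), `n_hits`,
#'   `n_ligands`.
#' @export
topkHits <- function(grid, k = 1L) {
  mask <- knownMask(grid)
  if (is.null(mask))
    .err("ppiDataError", "top-k hits require a known-interaction mask")
  s <- gridScores(grid)
  hasKnown <- rowSums(mask) > 0
  if (any(!hasKnown))
    warning(sprintf("excluding %d ligand(s) with no known receptor",
                    sum(!hasKnown)), call. = FALSE)
  ligs <- rownames(s)[hasKnown]
  hit <- vapply(ligs, function(l) {
    o <- order(-s[l, ], colnames(s))
    any(mask[l, o[seq_len(min(k, ncol(s)))]])
  }, TRUE)
  list(hits = data.frame(ligand = ligs, hit = unname(hit),
                         stringsAsFactors = FALSE),
       n_hits = sum(hit), n_ligands = length(ligs))
}

#' ROC over the flattened selectivity grid
#'
#' Labels come from the known-interaction mask; delegates to [rocAuc()]
#' and [rocCurve()].
#'
#' @param grid a [SelectivityGrid-class] with a known mask containing both
#'   classes.
#' @return list with `auc` and `curve`.
#' @export
gridRoc <- function(grid) {
  mask <- knownMask(grid)
  if (is.null(mask))
    .err("ppiDataError", "grid ROC requires a known-interaction mask")
  s <- as.numeric(gridScores(grid))
  l <- as.logical(mask)
  list(auc = rocAuc(s, l), curve = rocCurve(s, l))
}
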