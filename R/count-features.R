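# Structural "counting" features over the interface. All members are
# size-independent by construction (counts and proportions over interface
# residues/pairs only): features that scale with total protein size would
# leak the decoy generator's size bias and are excluded from the manifest.

#' Contact-pair counts by chemical class
#'
#' Counts interface pairs by the primary-class combination of the two
#' residues (charged / polar / hydrophobic; glycine and proline count as
#' special and only contribute to the total), plus aromatic-aromatic pairs
#' and salt bridges (one charged+, one charged- residue).
#'
#' @param model a [ComplexModel-class].
#' @param iface an [InterfaceMap-class].
#' @return named numeric vector of pair counts, including `n_contact_pairs`.
#' @export
contactPairCounts <- function(model, iface) {
  p <- iface@pairs
  aa <- model@residues$aa
  out <- c(n_contact_pairs = nrow(p),
           cp_charged_charged = 0, cp_charged_polar = 0,
           cp_charged_hydrophobic = 0, cp_polar_polar = 0,
           cp_polar_hydrophobic = 0, cp_hydrophobic_hydrophobic = 0,
           cp_aromatic_aromatic = 0, cp_saltbridge = 0)
  if (!nrow(p)) return(out)
  c1 <- vapply(aa[p[, 1L]], .primaryClass, "")
  c2 <- vapply(aa[p[, 2L]], .primaryClass, "")
  key <- paste(pmin(c1, c2), pmax(c1, c2), sep = "_")
  add <- function(nm, val) out[nm] <<- out[nm] + val
  add("cp_charged_charged", sum(key == "charged_charged"))
  add("cp_charged_polar", sum(key == "charged_polar"))
  add("cp_charged_hydrophobic", sum(key == "charged_hydrophobic"))
  add("cp_polar_polar", sum(key == "polar_polar"))
  add("cp_polar_hydrophobic", sum(key == "hydrophobic_polar"))
  add("cp_hydrophobic_hydrophobic", sum(key == "hydrophobic_hydrophobic"))
  arom <- function(x) vapply(x, function(a)
    "aromatic" %in% .AA_CLASSES[[a]], TRUE)
  add("cp_aromatic_aromatic", sum(arom(aa[p[, 1L]]) & arom(aa[p[, 2L]])))
  chg <- function(x) vapply(x, function(a) {
    cl <- .AA_CLASSES[[a]]
    if ("charged+" %in% cl) 1L else if ("charged-" %in% cl) -1L else 0L
  }, 1L)
  s1 <- chg(aa[p[, 1L]]); s2 <- chg(aa[p[, 2L]])
  add("cp_saltbridge", sum(s1 * s2 == -1L))
  out
}

#' Structural counting feature block
#'
#' The 33 counting features: interface residue counts (total and per
#' entity), per-class counts and proportions over the interface union
#' (charged is D/E/K/R), contact-pair counts by class combination, and
#' secondary-structure composition of the interface (per entity and
#' overall, including the overall beta-strand proportion
#' `prop_iface_beta`). Empty interfaces give all counts 0 and proportion
#' sentinel 0.
#'
#' @param model a [ComplexModel-class].
#' @param iface an [InterfaceMap-class] from the same model.
#' @param ssLabels per-residue secondary-structure labels (H/E/C) from
#'   [assignSecondaryStructure()]; computed if NULL.
#' @return named numeric vector of the 33 features, manifest order.
#' @export
countingFeatureBlock <- function(model, iface, ssLabels = NULL) {
  if (is.null(ssLabels)) ssLabels <- assignSecondaryStructure(model)
  aa <- model@residues$aa
  s1 <- iface@ifaceSet1
  s2 <- iface@ifaceSet2
  un <- c(s1, s2)
  nu <- length(un)
  inClass <- function(idx, cls) {
    if (!length(idx)) return(0L)
    sum(vapply(aa[idx], function(a) cls %in% .AA_CLASSES[[a]], TRUE))
  }
  nChgPos <- inClass(un, "charged+")
  nChgNeg <- inClass(un, "charged-")
  nPolar <- inClass(un, "polar")
  nHydro <- inClass(un, "hydrophobic")
  nArom <- inClass(un, "aromatic")
  prop <- function(x) if (nu) x / nu else 0
  ssProp <- function(idx, lab) {
    if (!length(idx)) return(0)
    mean(ssLabels[idx] == lab)
  }
  cp <- contactPairCounts(model, iface)
  c(n_iface_total = nu,
    n_iface_e1 = length(s1),
    n_iface_e2 = length(s2),
    n_charged_interface = nChgPos + nChgNeg,
    n_charged_pos_interface = nChgPos,
    n_charged_neg_interface = nChgNeg,
    n_polar_interface = nPolar,
    n_hydrophobic_interface = nHydro,
    n_aromatic_interface = nArom,
    n_gly_interface = if (nu) sum(aa[un] == "G") else 0L,
    n_pro_interface = if (nu) sum(aa[un] == "P") else 0L,
    prop_charged_iface = prop(nChgPos + nChgNeg),
    prop_polar_iface = prop(nPolar),
    prop_hydrophobic_iface = prop(nHydro),
    prop_aromatic_iface = prop(nArom),
    cp["n_contact_pairs"],
    mean_pairs_per_iface_residue = if (nu) 2 * nrow(iface@pairs) / nu else 0,
    cp[c("cp_charged_charged", "cp_charged_polar",
         "cp_charged_hydrophobic", "cp_polar_polar",
         "cp_polar_hydrophobic", "cp_hydrophobic_hydrophobic",
         "cp_aromatic_aromatic", "cp_saltbridge")],
    prop_iface_helix_e1 = ssProp(s1, "H"),
    prop_iface_beta_e1 = ssProp(s1, "E"),
    prop_iface_coil_e1 = ssProp(s1, "C"),
    prop_iface_helix_e2 = ssProp(s2, "H"),
    prop_iface_beta_e2 = ssProp(s2, "E"),
    prop_iface_coil_e2 = ssProp(s2, "C"),
    prop_iface_beta = ssProp(un, "E"),
    prop_iface_helix = ssProp(un, "H"))
}
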