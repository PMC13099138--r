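# Prediction-confidence feature block, including the two bespoke PAE
# statistics (worst-quarter interfacial PAE, best-quarter interchain PAE).

#' PAE value conventions
#'
#' PAE matrices are not symmetric; pair statistics combine the two
#' directions with the `mean` policy by default (`pae[i,j]` and `pae[j,i]`
#' averaged). The empty-interface sentinel for PAE statistics is 31.75
#' (the conventional PAE ceiling), pushing no-contact models toward decoy
#' scores; interface pLDDT sentinels are 0.
#'
#' @name pae-conventions
NULL

PAE_CEILING <- 31.75

.paePolicy <- function(pae, i, j, policy) {
  switch(policy,
         mean = (pae[cbind(i, j)] + pae[cbind(j, i)]) / 2,
         max = pmax(pae[cbind(i, j)], pae[cbind(j, i)]),
         min = pmin(pae[cbind(i, j)], pae[cbind(j, i)]),
         .err("ppiConfigError", "unknown PAE direction policy '%s'", policy))
}

#' PAE values over interacting residue pairs
#'
#' One value per interface pair, combining the two matrix directions per
#' the policy.
#'
#' @param conf a [ConfidenceBundle-class] paired with the model.
#' @param iface an [InterfaceMap-class].
#' @param policy direction policy: `"mean"` (default), `"max"`, `"min"`.
#' @return numeric vector (length = number of pairs; empty when the
#'   interface is empty, with attribute `empty = TRUE`).
#' @export
interactingPairPae <- function(conf, iface, policy = "mean") {
  p <- iface@pairs
  if (!nrow(p))
    return(structure(numeric(0), empty = TRUE))
  .paePolicy(conf@pae, p[, 1L], p[, 2L], policy)
}

#' PAE values over all cross-entity residue pairs
#'
#' @param conf a [ConfidenceBundle-class].
#' @param model the paired [ComplexModel-class].
#' @param policy direction policy (see [interactingPairPae()]).
#' @return numeric vector of length N1 x N2.
#' @export
allInterchainPae <- function(conf, model, policy = "mean") {
  if (nrow(conf@pae) != nResidues(model))
    .err("ppiPairingError",
         "PAE dimension %d does not match model residue count %d",
         nrow(conf@pae), nResidues(model))
  ent <- .entityVec(model)
  i1 <- which(ent == 1L)
  i2 <- which(ent == 2L)
  g <- expand.grid(i = i1, j = i2)
  .paePolicy(conf@pae, g$i, g$j, policy)
}

#' Mean of the top quarter of values
#'
#' Selects k = ceiling(n/4) values (the highest or the lowest quarter) and
#' returns their arithmetic mean.
#'
#' @param vals numeric vector (non-empty).
#' @param mode `"highest"` or `"lowest"`.
#' @return scalar mean of the selected quarter.
#' @export
#' @examples
#' topQuarterMean(1:8, "highest")  # mean of 7, 8 -> 7.5
#' topQuarterMean(1:8, "lowest")   # mean of 1, 2 -> 1.5
topQuarterMean <- function(vals, mode = c("highest", "lowest")) {
  mode <- match.arg(mode)
  n <- length(vals)
  if (!n)
    .err("ppiMetricError", "top-quarter mean undefined for empty input")
  k <- max(1L, ceiling(n / 4))
  s <- sort(vals, decreasing = (mode == "highest"))
  mean(s[seq_len(k)])
}

#' Prediction-confidence feature block
#'
#' The 7 confidence features: worst-quarter interfacial PAE
#' (`ipae_top_quarter`), best-quarter interchain PAE (`tpae_top_quarter`),
#' mean interchain PAE, mean interface pLDDT, minimum of the two entity
#' mean pLDDTs, pTM and iPTM. Empty interfaces yield the sentinel scheme
#' (PAE statistics 31.75, interface pLDDT 0).
#'
#' @param model a [ComplexModel-class].
#' @param conf the paired [ConfidenceBundle-class].
#' @param iface an [InterfaceMap-class] computed from `model`.
#' @param policy PAE direction policy.
#' @return named numeric vector of the 7 features, manifest order.
#' @export
confidenceFeatureBlock <- function(model, conf, iface, policy = "mean") {
  ipv <- interactingPairPae(conf, iface, policy)
  allv <- allInterchainPae(conf, model, policy)
  ent <- .entityVec(model)
  ifaceAll <- c(iface@ifaceSet1, iface@ifaceSet2)
  c(ipae_top_quarter = if (length(ipv)) topQuarterMean(ipv, "highest")
                       else PAE_CEILING,
    tpae_top_quarter = if (length(allv)) topQuarterMean(allv, "lowest")
                       else PAE_CEILING,
    mean_interchain_pae = if (length(allv)) mean(allv) else PAE_CEILING,
    mean_iface_plddt = if (length(ifaceAll)) mean(conf@plddt[ifaceAll])
                       else 0,
    min_entity_mean_plddt = min(mean(conf@plddt[ent == 1L]),
                                mean(conf@plddt[ent == 2L])),
    ptm = conf@ptm,
    iptm = conf@iptm)
}
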