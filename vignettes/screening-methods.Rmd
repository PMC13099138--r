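---
title: "Screening protein pairs with predicted complex models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening protein pairs with predicted complex models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PPIscreen)
```

## The problem and the model

Structure predictors emit a complex model for any pair of query
sequences, together with confidence data: per-residue pLDDT, the pairwise
predicted aligned error (PAE, in Å), and the global pTM/iPTM scores. The
screening question — *does this pair actually interact?* — is a binary
classification over such models. `PPIscreen` answers it with a
gradient-boosted tree classifier over 57 features of the model and its
confidence bundle, trained to separate models of genuine pairings from
models of *compelling decoys*: pairings assembled from close structural
analogs of real binding partners, which by construction look like real
complexes and cannot be dismissed on trivial grounds.

The classification unit is the *complex*, not the individual model: all
predicted models (typically five) of one pairing are scored and the
complex score is their maximum. A pairing is therefore called interacting
if *any* of its models looks convincing — mirroring how a practitioner
would triage a prospective screen, where individual models are sometimes
mis-docked.

### Entities, not chains

Every cross-"chain" notion in the package (interface, interchain PAE,
cross energies) is defined across two *entities* — chain groups — so
oligomeric screens reduce to the dimeric case. For a trimeric ligand
bound 3:1 by a receptor, the three ligand copies form entity 1 and the
receptor entity 2 (`groupEntities()`), and nothing downstream changes.

## The feature blocks

### Confidence (7 features)

The interface is the set of cross-entity residue pairs whose
representative atoms (Cβ; Cα for glycine) lie within **12 Å**
(inclusive — the boundary must be fixed for reproducibility). Over it the
package computes:

- `ipae_top_quarter` — the mean of the **highest** quarter of PAE values
  over interacting pairs. This is the single most informative feature: a
  confident interface keeps even its worst-quarter PAE low.
- `tpae_top_quarter` — the mean of the **lowest** quarter of PAE values
  over *all* cross-entity pairs, capturing whether any part of the
  relative placement is confident.
- `mean_interchain_pae`, `mean_iface_plddt`, `min_entity_mean_plddt`,
  `ptm`, `iptm`.

Three conventions required decisions, fixed once and shipped as package
constants:

- **Quarter rule**: k = ⌈n/4⌉, minimum 1 — guarantees a non-empty
  selection for any interface size.
- **PAE direction**: PAE matrices are asymmetric; pair statistics use the
  mean of `pae[i,j]` and `pae[j,i]`. A symmetric statistic avoids an
  arbitrary orientation choice.
- **Empty-interface sentinels**: PAE statistics take 31.75 (the
  conventional PAE ceiling) and interface-pLDDT statistics 0 when a model
  has no contacts. Sentinels, not missing values: a no-contact model is
  an informative negative and must flow through training, pushed firmly
  toward the decoy side of feature space.

### Structural counting (33 features)

Counts and proportions over interface residues and contact pairs:
interface sizes (total and per entity), residue-class counts (charged =
D/E/K/R; histidine is treated as polar, following the standard
convention), class-pair contact counts (charged–charged, salt bridges,
hydrophobic–hydrophobic, ...), and interface secondary-structure
composition, including the proportion of interfacial residues in
β-strands.

Two constraints shaped this block:

- **Size independence.** Nearest-analog decoy construction slightly
  favors larger proteins (larger analogs tend to score higher TM against
  any template), so any feature scaling with total protein size would let
  the classifier cheat by reading off the construction artifact. Every
  member of this block is a count or proportion over the interface only;
  a dedicated test appends residues far from the interface and asserts
  every feature is unchanged, and `sizeBiasReport()` measures the
  analog/template length-ratio distribution and flags manifest features
  correlating with length.
- **Self-contained secondary structure.** Labels come from a
  Kabsch–Sander-style assignment: backbone H-bonds scored with the
  electrostatic model E = 0.084·332·(1/rON + 1/rCH − 1/rOH − 1/rCN)
  kcal/mol (bond when E < −0.5, amide H placed 1 Å from N opposite the
  preceding carbonyl), helix from runs of ≥2 consecutive i→i+4 bonds,
  strand from parallel/antiparallel bridge patterns, everything else —
  including chain termini and incomplete backbones — degrades to coil.

### Interface energetics (17 features)

These are deliberately *analogs*, not a port, of a macromolecular force
field: a self-contained, parameter-light implementation keeps the package
dependency-free while preserving the physics the classifier needs
(packing quality, clashes, electrostatic and solvation complementarity).
Heavy atoms only — predicted models vary in hydrogen placement. Per
interfacial residue, interactions with the *other entity's* atoms are
summed for five terms:

| term | form | cutoff |
|---|---|---|
| LJ attractive/repulsive | ε[(σ/d)¹² − 2(σ/d)⁶], split at the minimum d = σ (attractive clamped at −ε inside, repulsive = LJ + ε) | 6 Å, linear switch over the last 0.5 Å |
| electrostatics | 332·qᵢqⱼ/(ε(d)·d), ε(d) = d | hard 10 Å |
| solvation | Gaussian occlusion: −ΔG_free·V_occ/(2π^1.5·λ·d²)·exp(−((d−r)/λ)²) | 6 Å, same switch |
| H-bond | cross-entity Kabsch–Sander bond energies, halved to each partner residue | bond criterion E < −0.5 |

Parameters are per-element classes (C/N/O/S σ, ε, ΔG_free, λ, volume)
with partial charges on the backbone amide dipole and the ionizable side
chains (carboxylates −0.5 per oxygen, Lys NZ +1, Arg guanidinium +1
distributed); `energyParams()` exposes the full table. The block reports
totals, per-interface-residue means (the identity `avg = total/n` is
tested), a weighted composite, and per-contact-pair means. The
discrimination property that matters — repulsion(clashed) >
repulsion(docked), |attraction(docked)| > |attraction(separated)| — is
asserted on generated pose triplets of the same chains.

## Model quality and the training filter

Training actives keep only models whose DockQ against the reference
structure is at least **0.23** (the "acceptable" threshold; the boundary
is inclusive). DockQ is implemented in full: Fnat (5 Å heavy-atom
contact definition), iRMS (backbone RMSD over the 10 Å native-interface
residues after interface superposition), LRMS (ligand backbone RMSD after
receptor superposition; receptor = larger entity), combined as

DockQ = (Fnat + 1/(1+(iRMS/1.5)²) + 1/(1+(LRMS/8.5)²)) / 3.

The scale constants are pinned in the package configuration. Validation
rows are filtered like training rows, but **test rows never are**: a
prospective screen cannot know DockQ (that would require the answer), so
held-out evaluation deliberately includes mis-docked actives.

Superpositions use the Kabsch algorithm (SVD with a proper-rotation
correction); degenerate (collinear) point sets are rejected rather than
silently resolved.

## Decoy construction

For a template complex, each component is replaced by its nearest
structural analog in the library, ranked by TM-score *normalized by the
template component's length* (the analog is being ranked *for* that
slot). TM alignment is a deterministic fragment-seeded procedure: gapless
length-20 Cα windows at stride 5 seed superpositions, each refined by
iterating "superpose on the close subset, rescore the full gapless
overlap" until stable, keeping the best seed. This is adequate for analog
ranking on libraries of intact folds; bit-parity with the reference
alignment program is a non-goal, and a global sequence-independent
aligner (which would add gapped alignments) was judged unnecessary for
the gapless synthetic regime the package ships with. TM ties within 1e-6
break lexicographically by id.

When the two chosen analogs together reconstitute a real pairing, the
second-best analog is substituted in *one* slot — whichever single-slot
substitution keeps the higher combined TM — falling back to second-best
in both; an exhaustive test asserts no emitted recipe ever reconstitutes
an active pairing. The crude superposition product is written for
inspection, and the component sequences are emitted as FASTA for
re-prediction, which is the canonical decoy for screening (and is outside
this package; synthetic confidence bundles stand in during tests).

## Partitioning, training, evaluation

- **Grouped splits.** Complexes (not rows) are randomly assigned 60/20/20
  to train/validation/test; stratified five-fold cross-validation
  likewise assigns whole complexes, stratifying by label at the complex
  level. `assertGroupIntegrity()` is a hard guard run in every test.
- **Classifier.** Gradient-boosted trees (binary logistic objective,
  single thread for determinism; defaults: depth 4, 100 rounds, learning
  rate 0.1, `colsample_bytree = 0.5`). The feature-subsampling default is
  a robustness decision: the confidence features are strongly redundant,
  and without subsampling every tree can saturate on one dominant split,
  leaving held-out values that fall in the training gap between class
  clusters on an arbitrary side of an arbitrary threshold. Subsampling
  forces the ensemble to vote across features, which empirically removes
  this failure mode on synthetic screens. A logistic baseline ships as a
  second backend for framework comparisons.
- **Backward selection** removes, at each step, the feature whose removal
  maximizes the cross-fold AUC, down to a target size (default 7) or
  until the AUC would drop more than a stated tolerance below the full
  model. **Hyperparameter search** grids over depth, rounds, learning
  rate, gamma, lambda and minimum child weight, scored by cross-fold AUC;
  neither ever touches test rows.
- **Evaluation.** Rank-based ROC AUC (midrank ties; tested against an
  O(n²) concordant-pair oracle), ROC curve points, and a
  threshold-performance table (FPR/TPR/FNR/TNR/precision/recall/F1 at 20
  standard operating points; precision at zero predicted positives is
  reported as 1 with recall 0). Confidence-only baselines are provided:
  iPTM passthrough and pDockQ = 0.724/(1+exp(−0.052(x−152.611))) + 0.018
  with x = mean interface pLDDT × ln(contact count), constants pinned
  from the published fit.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which the pipeline is exercised:

- `makeChain()` builds ideal backbones (N, Cα, C, O, Cβ) by
  natural-extension placement from per-state torsions: helix −57/−47,
  strand −139/135, coil randomized in the broad allowed region
  (φ ∈ [−150, −60], ψ ∈ [90, 180]). `makeSheetPair()` additionally ships
  a flat antiparallel two-strand ladder built from an untwisted
  (two-fold-screw, φ/ψ = −149/147) strand so that strand assignment has a
  deterministic positive fixture.
- `makeComplex()` realizes docked (minimum cross-entity representative
  distance in 4–8 Å, no heavy-atom overlap under 2.5 Å), clashed (≥5
  heavy-atom pairs under 2 Å) and separated (>30 Å) poses by a
  deterministic approach-line search under seeded orientations; the
  defining predicate is asserted after generation.
- `makeConfidence()` emulates the confidence signal: intra-entity PAE
  ≈ 2, cross-entity ≈ 4 (confident) or ≈ 25 (uncertain), Gaussian noise,
  clipped to [0, 31.75]; pLDDT uniform in 85–95; iPTM 0.8/0.2.
- `makeFeatureTable()` draws labeled tables with a stated standardized
  mean difference on the informative features and a shared within-complex
  random effect (variance 0.25 of a unit total), emulating the
  correlation among the five models of one prediction.

**What passing tests show — and don't.** The synthetic fixtures prove the
machinery: formulas match independent oracles, invariants (rigid
invariance, symmetry, monotonicity, group integrity) hold, the classifier
recovers planted signal (cross-fold AUC > 0.95 at effect size 3) and
finds none under the null (AUC ≈ 0.5 at effect size 0), and an end-to-end
synthetic screen separates actives from decoys. They do *not* show
real-world discrimination performance: real predicted models carry
correlated, non-Gaussian confidence structure, imperfect interfaces, and
decoys built from real folds; benchmark-scale AUCs require thousands of
externally predicted complexes and are outside the package's scope.

## Numerical conventions and problem sizes

- Residue indexing is positional (1..N in concatenated chain order, the
  natural convention in R) and aligned with the PAE matrix; author
  numbering is kept for reporting and model/native correspondence.
- All distance comparisons at stated cutoffs are inclusive.
- Altloc handling keeps the highest-occupancy conformer; insertion codes
  sort after their base residue; hydrogens are dropped on parsing.
- Missing pTM/iPTM are imputed as 0 with a warning (older score files
  omit them); missing Cβ on a non-glycine residue falls back to Cα with a
  warning rather than rebuilding an ideal Cβ.
- Every stochastic step takes an explicit integer seed; the test suite
  and the acceptance script derive all randomness from one seed. Test and
  acceptance problem sizes (chains of 15–30 residues, screens of 20–30
  complexes, 1–3 models each, 1000 split draws, 20 null seeds) were
  chosen to exercise every code path at desk scale with wide margins.

## Known limitations

- The energy terms are calibrated for discrimination, not for
  thermodynamic accuracy; their absolute scales are not comparable to any
  published force field.
- The TM-score alignment is gapless per seed offset; distantly related
  folds requiring long indels will score lower than a gapped aligner
  would report. For nearest-analog *ranking* this is benign, for absolute
  TM values near the 0.5 fold threshold it is conservative.
- The secondary-structure assignment implements the helix and bridge
  patterns only (no 3₁₀/π distinction, no bend/turn classes); residues in
  those states are labeled coil.
- `filterComplexMetadata()` implements the dataset predicates (resolution
  ≤ 3 Å, identity ≤ 30%, length ≤ 1550, chain ≥ 50, no homodimers or
  antibody complexes) as pure metadata filters; database acquisition is
  out of scope.
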