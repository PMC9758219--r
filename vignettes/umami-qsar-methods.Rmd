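---
title: "Umami QSAR: models, parameters and design choices"
author: "UmamiQSAR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Umami QSAR: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter and their
defaults, the choices made where the design was genuinely open, and
what the synthetic fixtures do and do not demonstrate.

## The problem

Umami is the fifth basic taste, elicited chiefly by glutamate and by
short glutamate/aspartate-rich peptides. Screening candidate molecules
experimentally is slow, so a structure-based classifier — a QSAR model
mapping 2D molecular descriptors to an umami / non-umami call — is a
practical pre-filter. The package implements the full workflow from raw
molecular notation to a gated, interpretable prediction.

## Input standardization

Inputs arrive as SMILES, InChI, or one-letter peptide sequences.
Peptides are assembled residue-by-residue into linear SMILES (free
N-terminal amine, free C-terminal acid, amide backbone; proline
contributes its pyrrolidine ring). All structures are then standardized
through one pipeline: parse, strip counter-ions and keep the largest
fragment, neutralize formal charges, remove stereochemical marks, and
canonicalize via the OpenBabel backend (ChemmineR/ChemmineOB).

Two standardization choices are deliberate:

* **Stereochemistry is dropped.** Only 2D descriptors are computed, so
  stereo marks can only introduce toolkit-version noise. Peptide
  assembly therefore emits flat α-carbons.
* **Issue levels.** A structure checker maps problems to
  `none`/`low`/`high`: valence violations or unparseable input are
  `high` (record excluded); salt stripping, isotope labels, or residual
  net charge are `low` (kept, flagged). Duplicate canonical SMILES
  within a split are reported but never auto-removed, leaving the data
  split untouched for reproducibility.

## Descriptor engine

The catalogue holds ~60 2D descriptors computed on the
hydrogen-suppressed graph: constitutional counts (atoms, bonds,
heteroatoms, rings, rotatable bonds, aromatic atoms), functional-group
counts (carboxyl, primary amine, amide, hydroxyl, thiol),
physicochemical properties from OpenBabel (MW, logP, MR, TPSA, H-bond
donor/acceptor counts), topological indices (Wiener, Harary, Zagreb,
Platt, Randić-type connectivity χ₀/χ₁, Balaban J, eccentric
connectivity, Kier κ₁–κ₃), centred and averaged Moreau–Broto
autocorrelations at lags 0–3 weighted by atomic mass and by Pauling
electronegativity, and the fragment complexity
`fragCpx = |B² − A² + A| + H/100`, implemented natively from its
closed form. A descriptor that cannot be evaluated yields a missing
cell, never an error; missingness is handled downstream.

The catalogue is intentionally smaller than the thousand-plus
descriptor sets of large Python toolkits; it spans the same families
(constitutional, topological, autocorrelation, physicochemical) while
remaining fully reproducible from this package's own code. Counts such
as "number of significant descriptors" therefore differ numerically
from results obtained with other toolkits' catalogues.

## Preprocessing

Fixed order, parameters learned on the training split only and frozen:

1. **Missing filter** — drop descriptors missing in more than 30% of
   training molecules (strictly greater).
2. **kNN imputation** — k = 20; distance is the mean squared
   difference over features observed in both rows; a missing cell takes
   the mean of its feature over the k nearest rows (all available rows
   when fewer than k qualify).
3. **Min–max normalization** to [0, 1]; constant features map to 0;
   test-time values outside the training range are clipped rather than
   extrapolated, keeping SVM kernels in the trained regime.

Class imbalance is handled by random duplication of minority rows to
exact parity. Oversampling happens inside each cross-validation
iteration on the nine training folds only — the evaluation fold is
never oversampled — and once on the full training split for the final
fit. Normalization precedes oversampling; duplicating rows cannot
change a min or a max, so the order is immaterial to the fitted
parameters but keeps the code single-pass.

## Univariate prioritization

For each descriptor the two-group moderated t-test shrinks the pooled
per-feature variance toward a prior estimated across features: the log
sample variances are moment-matched to a scaled-F model via
digamma/trigamma equations (Newton inversion of the trigamma), giving
prior degrees of freedom d₀ and prior variance s₀². When the dispersion
of log variances does not exceed its theoretical minimum, d₀ is
unbounded and s₀² is the mean variance; total degrees of freedom are
capped at the pooled residual value so p-values stay finite-sample
honest. q-values come from Benjamini–Hochberg step-up; descriptors at
q ≤ 0.05 are kept, ordered by q, then |log2FC|, then name (the last for
exact determinism). If fewer than five descriptors pass, the smallest-q
descriptors top the candidate list up, so the search never starts from
an empty pool. The log2 fold change adds ε = 1e−8 to both class means
when either is non-positive; on the normalized [0, 1] scale this only
guards exact zeros.

## The evolutionary search

A chromosome is a real vector in [0, 1]: four selector-enable bits
(Wilcoxon, kBest/ANOVA-F, MRMR, JMIM), four top-k genes (range
[5, 100], capped by the pool size), one inclusion gene per candidate
descriptor, a classifier gene, and three hyperparameter genes (C
log-uniform in [1e−2, 1e3], γ log-uniform in [1e−4, 1e1], trees in
[10, 500]). A descriptor is selected iff its gene exceeds 0.5 *and* it
lies in the union of the enabled selectors' top-k prefixes. Empty
selections are infeasible and score worst-case rather than crashing.

Defaults mirror the reference protocol: population 50, 100 generations,
two-point crossover 0.9, per-gene mutation 0.01, arithmetic crossover
off, five repeated runs, stratified 10-fold CV. Desk-scale work (tests,
examples) uses population ~20 and ~15 generations, which suffices for
the planted-signal fixtures; the repository's own checks state the
problem sizes they use.

Open points resolved here (the protocol description leaves them
ambiguous):

* **Pareto vs weights.** Both a Pareto archive and goal weights are
  part of the protocol without a stated interaction. Decision: Pareto
  front index is the primary rank (tournament selection, size 2) and
  the weighted sum (feature-min 5, ACC 10, F1 5, F2 1, precision 1,
  recall 10, AUC 1, model-size-min 1; minimization goals entered as
  1 − fraction) breaks ties within fronts and picks the final model.
  A perfect model with zero features and zero size scores the sum of
  the weights, 34.
* **Model-size normalization.** SVM support-vector counts are divided
  by the number of training rows; random-forest tree counts by the top
  of their gene range (10–500).
* **Fold plan fixed per search.** Folds and per-fold oversampling
  indices are computed once per search seed, so every chromosome is
  scored on identical data — fitness differences are model
  differences, and caching by decoded spec is sound.

SVM class probabilities are a deliberate deviation from the usual
`probability = TRUE` route: libsvm's internal probability training
consumes process-global C `rand()` state, so two identical fits in one
session return different probabilities. The package instead fits the
SVM without a probability model and calibrates decision values with a
deterministic logistic (Platt-type) fit, making identical seeds
byte-identical end to end. Random forests use vote fractions under a
seeded fit.

## Ensembles

The top archive members (default 5) are paired in all C(n,2)
combinations; each pair is scored by cross-validation in which both
members are refitted per fold and their held-out probabilities
averaged. The best pair by the weighted score becomes the final
ensemble. Prediction averages the two umami probabilities; a tie at
exactly 0.5 is called non-umami — the conservative choice for a
screening tool. Only pairs are formed, matching the reference protocol.

## Applicability domain

Training molecules are fingerprinted with 1024-bit radius-2 circular
(ECFP4-family) fingerprints, folded from the backend's native 4096-bit
output by OR over congruent positions. A query is inside the domain
when the mean Tanimoto similarity to its five most similar training
compounds is at least 0.4 (boundary inclusive; strictly below is
outside). When training compounds are scored against their own set,
one exact-identity match is removed first — otherwise every training
score's top-1 is trivially 1.0. The threshold is stored in the model
bundle and can be overridden; `scoreDistributions()` suggests one as
the pooled minimum rounded down to the nearest 0.05. The user-facing
predictor predicts-and-flags molecules outside the domain; the
screening command skips them, reporting "x/N inside, y/x umami".

## Interpretation

Shapley attributions are estimated by seeded permutation sampling
against the reference set's marginal background: for each probed row,
random permutations are walked from a random background row toward the
probed row, crediting each descriptor with the change in predicted
probability it causes. Per sampled permutation the credits sum exactly
to f(x) − f(z), so local accuracy holds up to Monte-Carlo error
(checked at ≤ 0.05 on fixture models). Sampling was chosen over exact
explainers to keep the contract model-agnostic across SVM and RF.
Importance is the mean absolute attribution; rankings are stable across
seeds at ~2000 samples. Selected features are clustered with
correlation distance 1 − |r| and average linkage — the convention for
feature dendrograms — with constant features placed at distance 1.

## Synthetic fixtures: what they show

Two generators make every stage testable without external data:

* **Planted descriptor matrices** — Gaussian features, an informative
  block mean-shifted by a chosen effect size in the positive class,
  optional within-block correlation ρ (default 0.3, emulating the
  heavy redundancy of real descriptor sets), MCAR missingness. Null
  calibration (effect 0 → ≤ 5% of features at q ≤ 0.05) and power
  (effect 2, 50/class → planted features recovered in ≥ 99% of seeds)
  are checked over hundreds of seeds. The optimizer check uses ρ = 0:
  with independent planted features, keeping several of them is
  Pareto-optimal; with a correlated block the parsimony goal correctly
  prunes duplicates, which is asserted separately (MRMR excludes an
  exact copy).
* **Rule-labeled peptides** — uniformly random sequences, lengths 2–8,
  labeled umami iff they contain ≥ 2 acidic residues (D/E), echoing
  the glutamate/aspartate association of umami taste. Uniform sampling
  yields only ~9% positives, so the generator tops the minority class
  up by rejection sampling (uniform conditional on class) to a 20%
  floor, emulating the roughly one-third minority fraction of curated
  umami datasets.

The acidic-residue rule is *descriptor-visible* (carboxyl and
heteroatom counts), so the end-to-end pipeline separates it nearly
perfectly. Passing these checks demonstrates that the machinery —
standardization, descriptors, statistics, search, ensembling, domain
gating — is wired correctly and is deterministic under a seed; it does
not demonstrate predictive performance on real taste data, where the
signal is weaker, noisier and spread over subtler descriptors.

## Numerical choices and degenerate inputs

* Ties in every ranking break on the lowest feature index / name, so
  stochastic-free components are exactly reproducible.
* Mutual information uses 10 equal-frequency bins (configurable);
  plug-in estimates are clamped at 0.
* Wilcoxon tests are exact for combined n ≤ 12 without ties, otherwise
  normal with tie correction; constant features take p = 1.
* Constant features: F score 0 (or ∞ if separation without variance),
  min-max maps to 0, correlation distance 1.
* Single-atom molecules (unsupported by the SDF container) are parsed
  directly; they carry empty fingerprints.
* A single query row cannot be kNN-imputed against itself; missing
  cells fall back to the normalized training midpoint 0.5.
* AUC with a single-class truth vector is undefined and reported NA
  (0.5 inside CV folds so means stay defined).

## Known limitations

* The descriptor catalogue is compact; models trained on it are not
  numerically comparable to models trained on thousand-descriptor
  toolkit catalogues, and published descriptor counts will not
  reproduce here.
* The applicability domain is fingerprint-similarity only; no
  leverage/descriptor-space variant.
* Only two-group contrasts are supported in the moderated t machinery
  (no covariates, no trend/robust variants).
* Ensembles average exactly two members; stacking and calibration are
  out of scope.
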