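# UmamiQSAR

Umami taste classification from molecular structure, for computational
chemists and food-science researchers building QSAR screening tools.
Given molecules as SMILES, InChI or peptide one-letter sequences with
binary umami / non-umami labels, the package standardizes the
structures, computes a 2D molecular-descriptor matrix, prioritizes
descriptors with a moderated t-test under FDR control, searches feature
subsets, classifier family and hyperparameters with a weighted
multi-objective Pareto evolutionary algorithm, averages pairs of models
into a probability ensemble, and gates predictions of new compounds
with a fingerprint-similarity applicability domain.

## The model

**Descriptors.** Each standardized molecule is mapped to a vector of 2D
descriptors computed on the hydrogen-suppressed molecular graph:
constitutional and functional-group counts, physicochemical properties
(logP, molar refractivity, TPSA, H-bond counts), topological indices
(Wiener, Zagreb, Randić connectivity, Balaban J, Kier shape),
mass- and electronegativity-weighted Moreau–Broto autocorrelations, and
the fragment complexity

    fragCpx = |B² − A² + A| + H/100

over heavy atoms A, heavy-atom bonds B and heteroatoms H.

**Univariate prioritization.** For every descriptor the two-group
moderated t statistic shrinks the per-feature variance s²_g toward an
empirical-Bayes prior (d₀, s₀²) estimated across all features by
digamma/trigamma moment matching:

    s̃² = (d₀·s₀² + d_g·s²_g)/(d₀ + d_g),
    t = (x̄₊ − x̄₋) / (s̃·√(1/n₊ + 1/n₋)),

with two-sided p-values on d₀ + d_g degrees of freedom and
Benjamini–Hochberg q-values; descriptors with q ≤ 0.05 enter the search.

**Evolutionary model search.** A chromosome encodes which of four
feature-selection methods (Wilcoxon rank-sum, ANOVA-F "kBest", MRMR,
JMIM) are active, their top-k depths, per-feature inclusion genes, the
classifier family (RBF-SVM or random forest) and its hyperparameters
(C, γ, number of trees). Fitness is stratified 10-fold cross-validation
with minority oversampling inside the nine training folds only;
solutions are ranked by Pareto front first and by the weighted goal sum
second (feature minimization 5, ACC 10, F1 5, F2 1, precision 1,
recall 10, AUC 1, model-size minimization 1). The all-time
non-dominated archive is kept; the top archive members are paired into
ensembles whose class probabilities are averaged, and the best pair by
cross-validated score becomes the final model.

**Applicability domain.** 1024-bit radius-2 circular (Morgan-type)
fingerprints of the training set; a query is inside the domain when the
mean Tanimoto similarity to its 5 most similar training compounds is at
least 0.4.

## Worked example

```r
library(UmamiQSAR)

# rule-labeled random peptides: >= 2 acidic residues (D/E) => umami
peps <- makePeptideSet(200, lengthRange = c(2, 8), seed = 31)
ms   <- makeMoleculeSet(peps)

cfg <- optimizerConfig(population = 20, generations = 15,
                       nFolds = 10, nRuns = 1, seed = 31)
bundle <- trainUmamiModel(ms, config = cfg)
bundle$metricsTable
#>        set acc spec sens f1 f2 auc     sd
#> 1 training   1    1    1  1  1   1     NA
#> 2       cv   1    1    1  1  1   1      0
#> 3     test   1    1    1  1  1   1     NA

predictUmami(bundle, c(q1 = "EEK", q2 = "GGG"), format = "fasta")[,
  c("id", "in_domain", "prediction", "probability_umami")]
#>   id in_domain prediction probability_umami
#> 1 q1      TRUE      Umami       0.811078411
#> 2 q2     FALSE  Non-umami       0.002601629
```

The metrics table rows are the three evaluation regimes: fit on the
oversampled training split scored on itself, the 10-fold
cross-validation mean (with the mean per-metric standard deviation),
and the untouched held-out test split. The acidic-residue rule is fully
visible to the descriptor set (carboxyl-group and heteroatom counts),
so the desk-scale pipeline separates it essentially perfectly;
real taste data are far noisier — see the vignette for what this
fixture does and does not demonstrate.

A shell entry point wrapping the same functions is installed at
`inst/scripts/umami-cli.R` (`train`, `predict`, `screen` subcommands).

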