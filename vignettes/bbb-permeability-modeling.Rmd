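---
title: "Modeling blood-brain barrier permeability (logBB) with bbbqsar"
author: "bbbqsar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling blood-brain barrier permeability (logBB) with bbbqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbqsar)
```

## The problem

The blood-brain barrier (BBB) is a selective endothelial membrane between
the systemic circulation and the central nervous system. For a CNS drug
candidate, the quantity of interest is logBB, the base-10 logarithm of the
ratio of a compound's steady-state brain concentration to its blood
concentration. Compounds with logBB at or above the conventional cutoff of
-1 are regarded as BBB-permeable; below it, nonpermeable. Measuring logBB
in vivo is slow and expensive, which motivates quantitative
structure-activity relationship (QSAR) models that predict it from computed
molecular descriptors.

`bbbqsar` implements the full model-construction workflow as a reusable
toolkit: similarity-based dataset curation, 2D descriptor computation,
correlation-based feature selection, an eight-learner regression benchmark
under 10-fold cross-validation with grid search, and prediction plus
binary classification of query compounds.

## Dataset curation by fingerprint similarity

Congeneric compounds inflate apparent model performance: a test fold that
contains a close analogue of a training compound is not an independent
test. Curation therefore removes near-duplicates by Tanimoto similarity

$$T(a, b) = \frac{N_c}{N_a + N_b - N_c},$$

where $N_a$ and $N_b$ count the on-bits of the two fingerprints and $N_c$
the bits on in both. Fingerprints are circular (Morgan) fingerprints,
radius 2, folded to 1024 bits -- the open ECFP4-equivalent. The
implementation hashes per-atom invariants (element, degree, bond-order
sum, implicit hydrogen count, formal charge) over the OpenBabel-parsed
molecular graph and iteratively rehashes each atom with its neighbours'
identifiers, once per radius step. Different fingerprint software dialects
place environments on different bits, so absolute bit patterns are not
comparable across toolkits; the similarity *structure* (homologs similar,
unrelated scaffolds dissimilar) is what the workflow relies on, and that is
what the test suite checks.

Deduplication is a leader-style greedy pass in input order: a compound is
kept iff its similarity to every previously kept compound is at most the
cutoff (default 0.85). The comparison is strict -- a pair at exactly the
cutoff is kept -- and which member of a similar pair survives is resolved
deterministically in favour of the earlier record. Both choices are
genuinely open in the protocol this package operationalizes; the greedy
leader pass was chosen because it is order-deterministic, runs in one
sweep, and guarantees the kept set has no pair above the cutoff. An
independent test set is screened with the same rule *against the training
set* (`screen_against_reference()`), never the other way around, so the
training set is unchanged and test compounds similar to training material
are excluded as leakage.

Two all-zero fingerprints would give the indeterminate form 0/0; their
similarity is defined as 0 and such molecules are flagged, since an empty
fingerprint carries no evidence of similarity.

## Descriptors

`compute_descriptors()` produces a compounds-by-descriptors numeric matrix
of roughly 40 two-dimensional descriptors: OpenBabel physicochemical
properties (molecular weight, logP, topological polar surface area, molar
refractivity, hydrogen-bond donor/acceptor counts), ring and aromatic-ring
counts, twelve functional-group counts, and constitutional/topological
statistics from the molecular graph (atom and bond counts by type,
branching, heteroatom fraction). A descriptor that fails for a molecule is
`NA`, never silently zero, and `prune_missing()` removes every column with
at least one missing or non-finite entry -- infinities from degenerate
descriptor formulas are as unusable as missing values, so both prune.

Three-dimensional descriptors require conformer embedding. The only
conformer generator available to this stack is not deterministic across
runs, and irreproducible features would poison every downstream
reproducibility guarantee, so the 3D set is deliberately omitted:
`include_3d = TRUE` raises an error instead of returning values that
cannot be regenerated. The descriptor count is far below the ~1650 of a
full descriptor-software install; matching that inventory is a non-goal --
the workflow's statistical machinery is independent of how many columns
enter it.

Features are standardized to zero mean and unit sample variance
(`fit_scaler()` / `apply_scaler()`, $n-1$ denominator). Zero-variance
columns are dropped before scaling. By default the scaler is refit inside
each cross-validation fold on the training part only, which is the
leakage-free protocol; `prescale = TRUE` reproduces the older convention of
scaling once on the full dataset before cross-validation. The distinction
rarely moves results (Pearson correlations, and hence the feature filter,
are scale-invariant), but the default is the defensible one.

## Correlation-based feature selection

Redundant descriptors carry the same information twice. The filter
computes the absolute Pearson correlation of every descriptor with logBB
(its *relevance*) and visits descriptors in decreasing relevance order,
keeping a descriptor iff its absolute pairwise correlation with every
already-kept descriptor is at most the threshold. This greedy order makes
the "keep the member more correlated with the target" rule hold globally,
not only pairwise, and two invariants follow by construction: no kept pair
exceeds the threshold, and every dropped descriptor conflicted with a kept
descriptor of at least its relevance. Absolute values are used on both
axes -- a strong negative correlation is as redundant, and as informative,
as a strong positive one. Relevance ties break lexicographically by name
so selection is deterministic.

`sweep_thresholds()` evaluates thresholds 0.1-0.9 (step 0.1) by running
the filter and then k-fold cross-validation of a chosen learner on each
selected set. One fold partition, derived from the seed alone, is shared
by all thresholds, so the comparison is paired; the chosen threshold
maximizes mean CV $R^2$, with ties broken toward the smaller feature set.
Feature count is non-decreasing in the threshold (a looser threshold never
removes more), which the tests assert.

## Learners and cross-validation

Eight regression learners sit behind one interface: LightGBM, random
forest, k-nearest neighbours, multiple linear regression, support vector
regression (RBF), AdaBoost.R2, XGBoost, and a single-hidden-layer neural
network. Standard implementations are used wherever the R ecosystem
provides one (`ranger`, `caret::knnreg`, `stats::lm.fit`, `e1071::svm`,
`xgboost`, `nnet`). Two need a word:

* **LightGBM** runs through the LightGBM library's Python build via a
  small batch subprocess, pinned to one thread, a fixed seed and
  deterministic histogram construction; the fitted model travels as the
  LightGBM text dump inside the R model object, so persistence is plain
  text and predictions are reproducible across sessions.
* **AdaBoost.R2** (boosting for regression with the linear loss) has no
  maintained R implementation, so it is authored here over `rpart`
  regression trees: stage weights from the weighted relative absolute
  error, early stop at average loss 0.5, prediction by the weighted median
  of the stage trees.

Cross-validation shuffles row indices with a single integer seed and cuts
the permutation into k contiguous folds, so the partition is a pure
function of (n, k, seed) -- this is what lets the threshold sweep pair its
comparisons. Per fold, the scaler is refit on the training part, the
learner fit with the shared seed, and held-out $R^2$ and MSE recorded;
the record keeps per-fold values, their arithmetic means, the fold
partition and the out-of-fold predictions. `grid_search()` enumerates the
Cartesian product of a hyperparameter grid in deterministic order,
cross-validates every point on the same folds, takes the highest mean CV
$R^2$ (first point wins ties), and refits on all rows. Default grids ship
in `inst/config/default_grids.yaml` and are deliberately modest; any grid
can be overridden per call. The ANN default hidden-layer size is
`min(64, n_features)` with deterministic seeded initialization.

## Evaluation

Regression quality is the coefficient of determination and mean squared
error,

$$R^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2},
\qquad \mathrm{MSE} = \frac{1}{n}\sum_i (y_i - \hat y_i)^2,$$

with the total sum of squares about the mean of the *observed* values --
the conventional definition, used here throughout.

For qualitative use, predicted and observed logBB are binarized at the
cutoff: $\mathrm{logBB} \ge -1$ is permeable, with the boundary itself
classified permeable ("permeable" is the positive class). From the
confusion counts the package reports sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, accuracy, positive and negative predictive value, and the
Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

which equals the Pearson correlation of the two binary label vectors -- a
property the test suite verifies on hundreds of random confusion tables.
Any metric whose denominator is zero is reported as *absent with a
reason*, never silently 0 or 1: a degenerate evaluation set (say, all
positive) must not masquerade as a perfect classifier.

## The synthetic data generators

Because the workflow's original compound collection is not redistributable,
the package ships generators that reproduce the *statistical structure* the
workflow assumes, so every stage is testable offline.

`make_smiles_series()` emits homologous alkane/alcohol/alkylbenzene series:
within a series, adjacent members share almost all circular-fingerprint
environments (Tanimoto near or at 1 -- deduplication's discard cases),
while cross-series pairs fall well below 0.85 (the keep cases).
`make_molecule_dataset()` crosses ring scaffolds with common substituents
into up to 130 diverse small molecules, computes their real descriptors,
and assigns logBB from a fixed linear rule on logP, molecular weight and
polar surface area plus Gaussian noise (sd 0.3 logBB units) -- lipophilic
helps, size and polarity hurt -- centred so both permeability classes are
populated around the -1 cutoff.

`make_regression_dataset()` builds the descriptor-table analogue: each
signal feature $z_j \sim N(0,1)$ heads a block that also contains
`clones_per_block` copies $\rho z_j + \sqrt{1-\rho^2}\,\varepsilon$, so
each clone correlates with its base at exactly $\rho$ (clones correlate
with each other at $\rho^2$). Because every clone conflicts with its base
directly, the correlation filter keeps exactly one column per block at any
threshold below $\rho$ -- an analytically known right answer. The response
is $y = \beta^\top z + N(0, \sigma)$ (plus an intercept of -0.5 so the
envelope of simulated logBB values straddles the -1 cutoff, matching the
roughly [-2.7, 1.7] range of curated experimental collections), giving the
analytic out-of-sample ceiling
$R^2_{\max} = \sum_j \beta_j^2 / (\sum_j \beta_j^2 + \sigma^2)$;
`noise_sd_for_ceiling()` inverts this. Defaults are three signal blocks
with coefficients (1, 0.8, 0.6), ten clones per block at $\rho = 0.95$,
and five unrelated noise features.

What these generators do *not* emulate: real descriptor distributions are
heavy-tailed and discretely supported, real redundancy is not
equicorrelated, and real logBB noise is heteroscedastic across assay
sources. Passing tests therefore demonstrate that the machinery is correct
and calibrated, not that any particular accuracy will be achieved on
experimental data.

## Numerical choices and problem sizes

* Tanimoto 0/0 (two empty fingerprints) is 0; the strict cutoff keeps
  exact-threshold pairs; duplicate canonical SMILES keep the first
  occurrence.
* Exactly collinear columns in the linear learner receive coefficient 0
  rather than propagating `NA` into predictions.
* Scaling inverts to machine precision; non-finite anywhere in a training
  matrix is a schema error, not a warning.
* Model archives embed a format version and loading refuses a mismatch.
* The validation suite runs cross-validation at n = 2000 (ceiling
  recovery, 10-fold, five seeds), 400-500 rows for filter and noise
  checks, and ~100 curated synthetic molecules for the end-to-end
  pipeline -- sizes at which the checked quantities are stable to well
  within the asserted tolerances while the whole suite stays fast.

## Known limitations

* Fingerprint bits are this package's Morgan dialect; Tanimoto values are
  comparable within the package, not bit-for-bit against other software.
* The 2D descriptor inventory (~40) is intentionally compact; descriptor
  availability, not modeling capacity, bounds accuracy on rich datasets.
* Charged and organometallic species get heuristic implicit-hydrogen
  counts; salts/mixtures receive no normalization beyond SMILES
  canonicalization.
* AdaBoost.R2 and the LightGBM bridge are single-threaded by design
  (determinism over speed).

## A complete run

```{r, eval = FALSE}
train <- make_molecule_dataset(110, seed = 1)
write.csv(train, "train.csv", row.names = FALSE)
res <- run_pipeline(list(
  input = "train.csv",
  learner = "xgboost", params = list(nrounds = 150),
  folds = 10, seed = 1, pcc_threshold = 0.8,
  outdir = "run"
))
res$cv            # per-fold and mean R2 / MSE
res$selection     # descriptors surviving the correlation filter
```

The same run is available from a shell via the bundled front-end:
`Rscript $(Rscript -e 'cat(system.file("cli/bbbqsar.R", package="bbbqsar"))') run --config run.yaml`.
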