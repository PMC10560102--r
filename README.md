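# bbbqsar

QSAR modeling of blood–brain barrier permeability expressed as **logBB**,
the log10 ratio of a compound's brain to blood concentration. The package
is for computational chemists and drug-discovery scientists who need to
build a logBB regression model from a SMILES+logBB collection and then
screen query compounds, classifying them as BBB-permeable at the
conventional cutoff logBB ≥ −1.

## What it does

The toolkit implements the standard model-construction workflow
end-to-end:

1. **Curation** — compounds are read from CSV/SMI, SMILES validated and
   canonicalized, and near-duplicates removed by Tanimoto similarity

   *T*(a,b) = N<sub>c</sub> / (N<sub>a</sub> + N<sub>b</sub> − N<sub>c</sub>)

   over 1024-bit radius-2 circular (Morgan/ECFP4-style) fingerprints, with
   a strict cutoff of 0.85. An independent test set is screened against the
   training set with the same rule to remove leakage.
2. **Featurization** — ~40 2D molecular descriptors (MW, logP, TPSA,
   H-bond counts, ring/atom/bond/functional-group statistics); descriptors
   with any missing or non-finite value are pruned; features standardized
   (per-CV-fold by default).
3. **Feature selection** — pairwise Pearson-correlation filtering: of two
   descriptors correlated beyond a threshold, the one with the lower
   |correlation with logBB| is dropped; thresholds 0.1–0.9 are swept and
   picked by cross-validated R².
4. **Modeling** — eight regression learners behind one interface
   (LightGBM, RF, kNN, MLR, SVM, AdaBoost.R2, XGBoost, ANN) with
   exhaustive grid search under seeded 10-fold cross-validation.
5. **Evaluation & prediction** — R² and MSE for regression; after
   binarization at logBB ≥ −1, confusion counts plus sensitivity,
   specificity, accuracy, NPV, PPV and the Matthews correlation
   coefficient. Query compounds get a predicted logBB and a
   permeable/nonpermeable call.

Every stage is deterministic under an integer seed, and the package ships
synthetic-data generators (congeneric SMILES series; block-correlated
descriptor tables with an analytic R² ceiling) so the whole workflow is
testable without any external download.

## Worked example

```r
library(bbbqsar)

train <- make_molecule_dataset(110, seed = 1)       # synthetic SMILES+logBB
write.csv(train, "train.csv", row.names = FALSE)
write.csv(data.frame(smiles = c("CCCCCCCCC", "OCCCCCCC", "OC(=O)C1CCNCC1")),
          "query.csv", row.names = FALSE)

res <- run_pipeline(list(
  input = "train.csv",
  learner = "xgboost", params = list(nrounds = 150),
  folds = 10, seed = 1, pcc_threshold = 0.8,
  query = "query.csv", outdir = "run"
))
```

which logs:

```
read: 110 rows, 110 parsed
curate: 98 kept, 12 discarded (Tanimoto > 0.85)
featurize: 41 descriptors after pruning
select: threshold 0.80 fixed, 24 features kept
train: xgboost, 10-fold CV mean R2 0.783, mean MSE 0.115
predict: 3 query compounds written
done: artifacts in run
```

Twelve of the 110 synthetic compounds are congeneric enough (Tanimoto
> 0.85) to be discarded; the correlation filter keeps 24 of 41
descriptors; the cross-validated model explains ~78% of the logBB variance
on this synthetic set. `run/predictions.csv` then holds one row per query:

```
"id","smiles","predicted_logbb","bbb_class"
"cmpd_0001","CCCCCCCCC",-0.086185,"permeable"
"cmpd_0002","CCCCCCCO",-0.914126,"permeable"
"cmpd_0003","OC(=O)C1CCNCC1",-2.45918,"nonpermeable"
```

Nonane and heptanol sit above the −1 cutoff (BBB-permeable); the polar,
charged-prone piperidine carboxylic acid falls well below it. The run
directory also contains `kept.csv`/`discards.csv` (curation decisions),
`features.csv`, `model.rds`, `evaluation.json` (regression and binarized
classification metrics with the confusion table) and `manifest.json`
(versions, parameters, input hashes, stage counts and timings). Omitting
`pcc_threshold` sweeps 0.1–0.9 and picks the best threshold by CV R²;
setting `grid:` runs an exhaustive hyperparameter search. A YAML file with
the same keys can replace the R list, and
`inst/cli/bbbqsar.R run --config run.yaml` drives the identical run from a
shell (subcommands `curate`, `screen`, `featurize`, `select`, `sweep`,
`train`, `predict`, `evaluate`, `synth` expose the individual stages).

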