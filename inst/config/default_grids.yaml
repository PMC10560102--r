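# Default hyperparameter grids for grid_search(). Values are candidate
# lists; the Cartesian product is searched exhaustively under k-fold CV.
# Override any grid through learner_spec(param_grid = ...).
lightgbm:
  learning_rate: [0.01, 0.05, 0.1]
  num_leaves: [15, 31, 63]
  n_estimators: [100, 300, 500]
  min_child_samples: [5, 20]
rf:
  num.trees: [300, 500]
  min.node.size: [1, 5]
knn:
  k: [3, 5, 7, 9]
svm:
  cost: [0.1, 1, 10]
  gamma: [0.01, 0.1]
xgboost:
  eta: [0.05, 0.1]
  max_depth: [3, 5]
  nrounds: [100, 300]
adaboost:
  n_estimators: [50, 100]
  max_depth: [2, 3]
ann:
  size: [16, 32, 64]
  decay: [0.001, 0.01, 0.1]
mlr: {}
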