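"""Batch backend for the lightgbm learner.

Called as a subprocess by the R package:
    fit     --train train.csv --params params.json --model model.txt
    predict --model model.txt --query query.csv --pred pred.csv

train.csv: header row, feature columns followed by a final column "y".
The model file is the LightGBM text dump, so it round-trips as plain text.
All settings are pinned for determinism: single thread, fixed seed,
row-wise histogram construction.
"""

import argparse
import json
import sys

import numpy as np
import lightgbm as lgb


def _read_csv(path):
    with open(path) as fh:
        header = fh.readline().strip().split(",")
    data = np.loadtxt(path, delimiter=",", skiprows=1, ndmin=2)
    header = [h.strip('"') for h in header]
    return header, data


def do_fit(args):
    header, data = _read_csv(args.train)
    if header[-1] != "y":
        sys.exit("train file must end with a 'y' column")
    X, y = data[:, :-1], data[:, -1]
    with open(args.params) as fh:
        p = json.load(fh)
    seed = int(p.get("seed", 42))
    booster = lgb.train(
        {
            "objective": "regression",
            "learning_rate": float(p.get("learning_rate", 0.1)),
            "num_leaves": int(p.get("num_leaves", 31)),
            "min_data_in_leaf": int(p.get("min_child_samples", 5)),
            "min_data_in_bin": 1,
            "feature_pre_filter": False,
            "deterministic": True,
            "force_row_wise": True,
            "num_threads": 1,
            "seed": seed,
            "verbosity": -1,
        },
        lgb.Dataset(X, label=y, params={"min_data_in_bin": 1,
                                        "feature_pre_filter": False}),
        num_boost_round=int(p.get("n_estimators", 100)),
    )
    booster.save_model(args.model)


def do_predict(args):
    booster = lgb.Booster(model_file=args.model)
    _, X = _read_csv(args.query)
    pred = booster.predict(X, num_threads=1)
    np.savetxt(args.pred, pred, fmt="%.12g")


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("mode", choices=["fit", "predict"])
    ap.add_argument("--model", required=True)
    ap.add_argument("--train")
    ap.add_argument("--query")
    ap.add_argument("--params")
    ap.add_argument("--pred")
    args = ap.parse_args()
    if args.mode == "fit":
        do_fit(args)
    else:
        do_predict(args)


if __name__ == "__main__":
    main()
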