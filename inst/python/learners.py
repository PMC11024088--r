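"""scikit-learn worker: RF / SVM fitting, CV-fold predictions, prediction.

Called as:  python learners.py <command> <request.json> <response.json>

The feature matrix is exchanged as a headerless CSV (rows = compounds);
labels are 0/1 with 1 = active (BBB-permeating).  Only out-of-fold /
held-out positive-class probabilities travel back: all metric computation
stays on the R side.

Commands:
  cv       {"x_path", "y", "family", "configs": [..], "k", "seed"}
           -> {"fold": per-sample fold id, "proba": per-config list of
               out-of-fold positive-class probabilities}
  train    {"x_path", "y", "family", "params", "seed", "model_path"}
  predict  {"model_path", "x_path"} -> {"proba": [...]}
"""
import json
import sys

import joblib
import numpy as np
from sklearn.ensemble import RandomForestClassifier
from sklearn.model_selection import StratifiedKFold
from sklearn.svm import SVC


def load_x(path):
    X = np.loadtxt(path, delimiter=",", ndmin=2)
    return X


def build(family, params, y, seed):
    params = dict(params or {})
    cw = params.pop("class_weight", None)
    if cw == "none":
        cw = None
    if family == "random_forest":
        md = params.get("max_depth")
        mf = params.get("max_features", "sqrt")
        if mf == "none":
            mf = None
        return RandomForestClassifier(
            n_estimators=int(params.get("n_estimators", 100)),
            max_depth=None if md in (None, "none") else int(md),
            max_features=mf,
            criterion=params.get("criterion", "gini"),
            class_weight=cw,
            random_state=seed,
            n_jobs=1,
        )
    if family in ("svm_rbf", "svm_poly"):
        return SVC(
            kernel="rbf" if family == "svm_rbf" else "poly",
            C=float(params.get("C", 1.0)),
            gamma=float(params.get("gamma", "0.1")),
            degree=int(params.get("degree", 3)),
            class_weight=cw,
            probability=True,
            random_state=seed,
        )
    raise ValueError("unknown family: %s" % family)


def pos_proba(clf, X):
    proba = clf.predict_proba(X)
    idx = int(np.where(clf.classes_ == 1)[0][0])
    return proba[:, idx]


def cmd_cv(req):
    X = load_x(req["x_path"])
    y = np.asarray(req["y"], dtype=int)
    k = int(req["k"])
    seed = int(req["seed"])
    skf = StratifiedKFold(n_splits=k, shuffle=True, random_state=seed)
    folds = list(skf.split(X, y))
    fold_id = np.empty(len(y), dtype=int)
    for i, (_, test_idx) in enumerate(folds):
        fold_id[test_idx] = i + 1
    per_config = []
    for params in req["configs"]:
        oof = np.full(len(y), np.nan)
        for train_idx, test_idx in folds:
            clf = build(req["family"], params, y[train_idx], seed)
            clf.fit(X[train_idx], y[train_idx])
            oof[test_idx] = pos_proba(clf, X[test_idx])
        per_config.append(oof.tolist())
    return {"fold": fold_id.tolist(), "proba": per_config}


def cmd_train(req):
    X = load_x(req["x_path"])
    y = np.asarray(req["y"], dtype=int)
    clf = build(req["family"], req.get("params"), y, int(req["seed"]))
    clf.fit(X, y)
    joblib.dump(clf, req["model_path"])
    return {"n_features": int(X.shape[1]), "n_samples": int(X.shape[0])}


def cmd_predict(req):
    clf = joblib.load(req["model_path"])
    X = load_x(req["x_path"])
    return {"proba": pos_proba(clf, X).tolist()}


def main():
    command, req_path, res_path = sys.argv[1], sys.argv[2], sys.argv[3]
    with open(req_path) as fh:
        req = json.load(fh)
    handler = {"cv": cmd_cv, "train": cmd_train, "predict": cmd_predict}[command]
    res = handler(req)
    with open(res_path, "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
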