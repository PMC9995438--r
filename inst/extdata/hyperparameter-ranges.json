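{
  "version": 1,
  "note": "Randomized-search ranges per algorithm. dist: loguniform|uniform|int|choice. 'refine' lists the parameters expanded into a local grid around the best random candidate.",
  "LR": {
    "params": {
      "alpha": {"dist": "uniform", "low": 0, "high": 1},
      "lambda": {"dist": "loguniform", "low": 1e-05, "high": 0.1}
    },
    "refine": ["lambda"]
  },
  "RF": {
    "params": {
      "num.trees": {"dist": "int", "low": 100, "high": 500},
      "mtry": {"dist": "int", "low": 4, "high": 32},
      "min.node.size": {"dist": "int", "low": 1, "high": 10},
      "sample.fraction": {"dist": "uniform", "low": 0.6, "high": 1}
    },
    "refine": ["num.trees", "mtry", "min.node.size"]
  },
  "XGB": {
    "params": {
      "nrounds": {"dist": "int", "low": 50, "high": 200},
      "eta": {"dist": "loguniform", "low": 0.03, "high": 0.3},
      "max_depth": {"dist": "int", "low": 3, "high": 8},
      "min_child_weight": {"dist": "int", "low": 1, "high": 10},
      "subsample": {"dist": "uniform", "low": 0.6, "high": 1},
      "colsample_bytree": {"dist": "uniform", "low": 0.5, "high": 1}
    },
    "refine": ["nrounds", "eta", "max_depth"]
  },
  "SVM": {
    "params": {
      "kernel": {"dist": "choice", "values": ["polynomial", "linear"]},
      "cost": {"dist": "loguniform", "low": 0.01, "high": 10},
      "degree": {"dist": "int", "low": 2, "high": 4}
    },
    "refine": []
  }
}
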