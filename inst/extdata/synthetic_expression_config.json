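{
  "data_path": "synthetic_expression_counts.csv",
  "metadata_path": "synthetic_expression_metadata.csv",
  "target_column": "condition",
  "problem_type": "classification",
  "data_type": "gene_expression",
  "expression_type": "COUNTS",
  "models": ["rf", "knn"],
  "hyper_tuning": "none",
  "seed": 7,
  "feature_selection": {
    "k": 10
  },
  "plots": ["cv_box", "confusion", "shap_bar"]
}
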