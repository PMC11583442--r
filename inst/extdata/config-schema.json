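{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "omicsml run configuration",
  "type": "object",
  "additionalProperties": false,
  "required": ["data_path", "metadata_path", "target_column", "problem_type"],
  "properties": {
    "data_path": { "type": "string", "description": "CSV, samples x features, first column = sample IDs" },
    "metadata_path": { "type": "string", "description": "CSV, first column = sample IDs" },
    "target_column": { "type": "string" },
    "problem_type": { "enum": ["classification", "regression"] },
    "data_type": {
      "enum": ["gene_expression", "microbiome", "metabolomic", "tabular", "none"],
      "default": "none"
    },
    "expression_type": {
      "enum": ["FPKM", "RPKM", "TMM", "TPM", "Log2FC", "COUNTS", "OTHER"],
      "description": "required iff data_type = gene_expression; COUNTS triggers TMM conversion"
    },
    "filter_sample_sd": { "type": ["number", "null"], "minimum": 0 },
    "filter_feature_min": {
      "type": ["object", "null"],
      "additionalProperties": false,
      "required": ["value", "samples"],
      "properties": {
        "value": { "type": "number" },
        "samples": { "type": "integer", "minimum": 0 }
      }
    },
    "collapse_tax": { "enum": ["k", "p", "c", "o", "f", "g", "s", null] },
    "min_reads": { "type": "integer", "minimum": 0, "default": 1000 },
    "norm_reads": { "type": "integer", "minimum": 0, "default": 1000 },
    "filter_abundance": { "type": "number", "minimum": 0, "default": 10 },
    "filter_prevalence": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.01 },
    "filter_microbiome_samples": {
      "type": ["array", "object", "null"],
      "description": "rule(s) {metadata column: category to remove}",
      "default": null
    },
    "remove_classes": { "type": ["array", "null"], "items": { "type": "string" } },
    "merge_classes": {
      "type": ["object", "null"],
      "description": "{new label: [old labels]}"
    },
    "test_size": { "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1, "default": 0.2 },
    "seed": { "type": "integer", "default": 42 },
    "feature_selection": {
      "type": ["object", "null"],
      "additionalProperties": false,
      "properties": {
        "variance_threshold": { "type": "number", "minimum": 0, "default": 0 },
        "k": { "oneOf": [{ "type": "integer", "minimum": 1 }, { "const": "auto" }, { "type": "null" }] },
        "auto_min": { "type": "integer", "minimum": 1 },
        "auto_max": { "type": "integer", "minimum": 3 }
      }
    },
    "balancing": { "enum": ["none", "oversample", "undersample"], "default": "none" },
    "models": {
      "type": "array",
      "items": { "enum": ["rf", "gradient_boosted_trees", "adaboost", "knn", "lightgbm_style"] }
    },
    "scoring": { "enum": ["accuracy", "precision", "f1", "auc", "mse", "mae", "mape", "r2"] },
    "hyper_tuning": { "enum": ["random", "grid", "none"], "default": "random" },
    "plots": {
      "type": "array",
      "items": {
        "enum": ["cv_box", "metric_bar", "confusion", "roc", "selection_curve",
                 "correlation", "joint", "shap_bar", "shap_dot", "permutation_bar"]
      },
      "default": []
    },
    "explanations": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "top_n": { "type": "integer", "minimum": 1, "default": 15 },
        "on": { "enum": ["train", "test", "both"], "default": "test" }
      }
    }
  }
}
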