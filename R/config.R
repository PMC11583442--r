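#' Run configuration
#'
#' A single JSON file drives a whole run. [parse_config()] validates it,
#' applies documented defaults, and fails fast on unknown keys (a typo in a
#' key name must never silently disable a filter). A JSON-schema document of
#' the accepted keys ships in `inst/extdata/config-schema.json`.
#'
#' @name config_cli
NULL

CONFIG_KEYS <- c(
  "data_path", "metadata_path", "target_column", "problem_type", "data_type",
  "expression_type", "filter_sample_sd", "filter_feature_min", "collapse_tax",
  "min_reads", "norm_reads", "filter_abundance", "filter_prevalence",
  "filter_microbiome_samples", "remove_classes", "merge_classes", "test_size",
  "seed", "feature_selection", "balancing", "models", "scoring",
  "hyper_tuning", "plots", "explanations"
)

config_error <- function(key, why) {
  stop("invalid configuration: '", key, "' ", why, call. = FALSE)
}

#' Parse and validate a JSON run configuration
#'
#' All defaults are applied (and reported in the `"applied_defaults"`
#' attribute for logging); all invariants are verified; unknown top-level
#' keys are rejected.
#'
#' @param path Path to a JSON configuration file, or a named list with the
#'   same structure.
#' @return A validated `oml_config` list.
#' @export
parse_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    tryCatch(
      jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
      error = function(e) stop("malformed JSON in ", path, ": ", conditionMessage(e), call. = FALSE)
    )
  } else {
    path
  }
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  for (key in c("data_path", "metadata_path", "target_column", "problem_type")) {
    if (is.null(raw[[key]])) config_error(key, "is required")
  }
  if (!raw$problem_type %in% c("classification", "regression")) {
    config_error("problem_type", "must be 'classification' or 'regression'")
  }

  applied <- character()
  default <- function(key, value) {
    if (is.null(raw[[key]])) {
      applied <<- c(applied, key)
      value
    } else {
      raw[[key]]
    }
  }

  cfg <- list(
    data_path = raw$data_path,
    metadata_path = raw$metadata_path,
    target_column = raw$target_column,
    problem_type = raw$problem_type,
    data_type = default("data_type", "none"),
    expression_type = raw$expression_type,
    filter_sample_sd = raw$filter_sample_sd,
    filter_feature_min = raw$filter_feature_min,
    collapse_tax = raw$collapse_tax,
    min_reads = default("min_reads", 1000),
    norm_reads = default("norm_reads", 1000),
    filter_abundance = default("filter_abundance", 10),
    filter_prevalence = default("filter_prevalence", 0.01),
    filter_microbiome_samples = raw$filter_microbiome_samples,
    remove_classes = raw$remove_classes,
    merge_classes = raw$merge_classes,
    test_size = default("test_size", 0.2),
    seed = default("seed", 42),
    feature_selection = raw$feature_selection,
    balancing = default("balancing", "none"),
    models = default("models", names(model_registry(raw$problem_type))),
    scoring = default(
      "scoring",
      if (raw$problem_type == "classification") "f1" else "mae"
    ),
    hyper_tuning = default("hyper_tuning", "random"),
    plots = default("plots", character()),
    explanations = default("explanations", list(top_n = 15, on = "test"))
  )

  if (!cfg$data_type %in% c("gene_expression", "microbiome", "metabolomic", "tabular", "none")) {
    config_error("data_type", "must be one of gene_expression, microbiome, metabolomic, tabular, none")
  }
  if (cfg$data_type == "gene_expression") {
    if (is.null(cfg$expression_type)) {
      config_error("expression_type", "is required when data_type = 'gene_expression'")
    }
    if (!cfg$expression_type %in% c("FPKM", "RPKM", "TMM", "TPM", "Log2FC", "COUNTS", "OTHER")) {
      config_error("expression_type", "is not a recognised expression type")
    }
  } else if (!is.null(cfg$expression_type)) {
    config_error("expression_type", "is only valid with data_type = 'gene_expression'")
  }
  if (!is.numeric(cfg$test_size) || cfg$test_size <= 0 || cfg$test_size >= 1) {
    config_error("test_size", "must be a proportion strictly between 0 and 1")
  }
  if (!is.numeric(cfg$filter_prevalence) || cfg$filter_prevalence < 0 || cfg$filter_prevalence > 1) {
    config_error("filter_prevalence", "must be a proportion in [0, 1]")
  }
  if (!is.null(cfg$filter_sample_sd) &&
    (!is.numeric(cfg$filter_sample_sd) || cfg$filter_sample_sd < 0)) {
    config_error("filter_sample_sd", "must be a non-negative number or null")
  }
  if (!is.null(cfg$filter_feature_min)) {
    fm <- cfg$filter_feature_min
    if (is.null(fm$value) || is.null(fm$samples)) {
      config_error("filter_feature_min", "must provide 'value' and 'samples'")
    }
  }
  if (!is.null(cfg$collapse_tax) && !cfg$collapse_tax %in% RANK_LETTERS) {
    config_error("collapse_tax", "must be one of k, p, c, o, f, g, s")
  }
  for (key in c("min_reads", "norm_reads", "filter_abundance")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 0) config_error(key, "must be non-negative")
  }
  if (!cfg$balancing %in% c("none", "oversample", "undersample")) {
    config_error("balancing", "must be none, oversample, or undersample")
  }
  if (cfg$balancing != "none" && cfg$problem_type != "classification") {
    config_error("balancing", "is only available for classification runs")
  }
  if (!cfg$hyper_tuning %in% c("random", "grid", "none")) {
    config_error("hyper_tuning", "must be random, grid, or none")
  }
  registry_names <- names(model_registry(cfg$problem_type))
  bad_models <- setdiff(cfg$models, registry_names)
  if (length(bad_models)) {
    config_error("models", paste0(
      "contains unknown model(s): ",
      paste(bad_models, collapse = ", ")
    ))
  }
  info <- METRIC_INFO[[cfg$scoring]]
  if (is.null(info)) config_error("scoring", "is not a recognised metric")
  if (info$type != cfg$problem_type) {
    config_error("scoring", paste0("is a ", info$type, " metric but problem_type is ", cfg$problem_type))
  }
  if (!is.null(cfg$feature_selection)) {
    fs <- cfg$feature_selection
    extra <- setdiff(names(fs), c("variance_threshold", "k", "auto_min", "auto_max"))
    if (length(extra)) config_error("feature_selection", paste0("has unknown key(s): ", paste(extra, collapse = ", ")))
    vt <- fs$variance_threshold %||% 0
    if (!is.numeric(vt) || vt < 0) config_error("feature_selection.variance_threshold", "must be >= 0")
    if (identical(fs$k, "auto")) {
      if (!is.null(fs$auto_min) && !is.null(fs$auto_max) && fs$auto_min >= fs$auto_max) {
        config_error("feature_selection", "requires auto_min < auto_max when k = 'auto'")
      }
    } else if (!is.null(fs$k) && (!is.numeric(fs$k) || fs$k < 1)) {
      config_error("feature_selection.k", "must be a positive integer or 'auto'")
    }
  }
  ex <- cfg$explanations
  if (!is.null(ex$on) && !ex$on %in% c("train", "test", "both")) {
    config_error("explanations.on", "must be train, test, or both")
  }
  cfg$explanations$top_n <- ex$top_n %||% 15
  cfg$explanations$on <- ex$on %||% "test"
  cfg$seed <- as.integer(cfg$seed)

  if (length(applied)) {
    message("parse_config: defaults applied for ", paste(applied, collapse = ", "))
  }
  structure(cfg, class = "oml_config", applied_defaults = applied)
}

#' @export
print.oml_config <- function(x, ...) {
  cat(
    "<oml_config>", x$problem_type, "on", x$data_type, "data | target:",
    x$target_column, "| models:", paste(x$models, collapse = ", "), "\n"
  )
  invisible(x)
}
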