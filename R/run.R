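#' Run modes
#'
#' Training executes the full pipeline in a fixed order -- load, omic
#' pre-processing, split, standardise, feature-select, balance,
#' tune/evaluate, best-model selection, plots, explanations -- and persists a
#' versioned run bundle (fitted transforms, selected features, fitted models,
#' results table). The other modes replay parts of a persisted bundle:
#' plotting regenerates figures, holdout evaluates the stored models on a new
#' labelled table, prediction applies the best model to unlabelled data.
#' Standardisation, selection and balancing are fitted on the training
#' partition only; test rows never influence a fitted transform.
#'
#' @name run_modes
NULL

#' Execute a training run
#'
#' @param config An `oml_config` (or path to a JSON config).
#' @param output_dir Directory for artifacts and the persisted bundle.
#' @param table,target Optional in-memory data (tests/programmatic use);
#'   by default read from `config$data_path` / `config$metadata_path`.
#' @return An `oml_run` object (invisibly also persisted under
#'   `output_dir`).
#' @export
run_training <- function(config, output_dir = NULL, table = NULL, target = NULL) {
  if (is.character(config) || !inherits(config, "oml_config")) {
    config <- parse_config(config)
  }
  seed <- config$seed
  if (is.null(table)) {
    table <- read_feature_table(config$data_path)
    metadata <- read_metadata(config$metadata_path)
    target <- extract_target(metadata, config$target_column, config$problem_type)
  } else {
    metadata <- target
    if (!"target" %in% names(target)) {
      target <- extract_target(metadata, config$target_column, config$problem_type)
    }
  }
  aligned <- align_samples(table, target)

  pre <- preprocess_omics(aligned$table, aligned$target, metadata, config)

  split <- split_train_test(pre$table, pre$target,
    test_size = config$test_size,
    seed = derive_seed(seed, 1)
  )
  y_train <- if (is.factor(split$train$target$target)) {
    droplevels(split$train$target$target)
  } else {
    split$train$target$target
  }
  y_test <- if (is.factor(y_train)) {
    factor(as.character(split$test$target$target), levels = levels(y_train))
  } else {
    split$test$target$target
  }

  qmap <- fit_quantile_map(split$train$table)
  train_std <- apply_quantile_map(qmap, split$train$table)
  test_std <- apply_quantile_map(qmap, split$test$table)

  fsel <- run_feature_selection(train_std, y_train, config$feature_selection,
    scoring = config$scoring, seed = derive_seed(seed, 2)
  )
  features <- fsel$features
  X_train <- ft_matrix(train_std)[, features, drop = FALSE]
  X_test <- ft_matrix(test_std)[, features, drop = FALSE]

  if (config$problem_type == "classification" && config$balancing != "none") {
    bal <- rebalance(X_train, y_train, config$balancing, seed = derive_seed(seed, 3))
    X_fit <- bal$X
    y_fit <- bal$y
  } else {
    X_fit <- X_train
    y_fit <- y_train
  }

  registry <- model_registry(config$problem_type, config$models)
  results <- lapply(registry, function(spec) {
    message("training ", spec$name, " (", config$hyper_tuning, " search)")
    res <- tune_and_fit(spec, X_fit, y_fit,
      search = config$hyper_tuning,
      scoring = config$scoring, seed = derive_seed(seed, 4)
    )
    evaluate_on_split(res, X_train, y_train, X_test, y_test)
  })

  results_table <- purrr::map_dfr(results, tidy)
  points <- purrr::map_dfr(results, function(r) {
    tibble::tibble(
      model = r$name,
      train = unname(r$train_metrics[[config$scoring]]),
      test = unname(r$test_metrics[[config$scoring]])
    )
  })
  best <- select_best(points, metric_orientation(config$scoring))
  best_result <- results[[best$winner]]

  expl_on <- config$explanations$on
  X_expl <- switch(expl_on,
    train = X_train,
    test = X_test,
    both = rbind(X_train, X_test)
  )
  y_expl <- switch(expl_on,
    train = y_train,
    test = y_test,
    both = if (is.factor(y_train)) {
      factor(c(as.character(y_train), as.character(y_test)), levels = levels(y_train))
    } else {
      c(y_train, y_test)
    }
  )
  explanations <- shapley_explanations(best_result$model, X_expl,
    top_n = config$explanations$top_n,
    background = X_train, seed = derive_seed(seed, 6)
  )
  permimp <- permutation_importance(best_result$model, X_expl, y_expl,
    metric = config$scoring, seed = derive_seed(seed, 8)
  )

  run <- structure(
    list(
      config = config, reports = pre$reports, split = split, qmap = qmap,
      features = features, selection_curve = fsel$curve,
      variance_removed = fsel$variance_removed,
      results = results, results_table = results_table, best = best,
      explanations = explanations, permimp = permimp,
      y_levels = if (is.factor(y_train)) levels(y_train) else NULL,
      data = list(
        X_train = X_train, X_test = X_test,
        y_train = y_train, y_test = y_test
      )
    ),
    class = "oml_run"
  )
  if (!is.null(output_dir)) write_outputs(run, output_dir)
  run
}

#' @export
print.oml_run <- function(x, ...) {
  cat(
    "<oml_run>", x$config$problem_type, "|",
    nrow(x$data$X_train), "train /", nrow(x$data$X_test), "test |",
    length(x$features), "features |", length(x$results), "models\n"
  )
  cat(
    "best model:", x$best$winner, "(", x$config$scoring, "test =",
    signif(x$results[[x$best$winner]]$test_metrics[[x$config$scoring]], 3), ")\n"
  )
  invisible(x)
}

#' Tidy a training run
#'
#' The results table: one row per model and metric with train, CV and test
#' values.
#'
#' @param x An `oml_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy oml_run
#' @export
tidy.oml_run <- function(x, ...) x$results_table

#' Glance at a training run
#'
#' @param x An `oml_run`.
#' @param ... Unused.
#' @return One row per model: scoring-metric summary plus the
#'   distance-to-ideal used for recommendation.
#' @method glance oml_run
#' @export
glance.oml_run <- function(x, ...) {
  dplyr::left_join(
    purrr::map_dfr(x$results, glance),
    dplyr::select(x$best$distances, "model", "D"),
    by = "model"
  ) |>
    dplyr::mutate(best = .data$model == x$best$winner)
}

#' Persist a run's artifacts and bundle
#'
#' Writes the results table CSV, explanation CSVs (exact file-name
#' templates), requested plots, a `best_model/` folder with the winner's
#' serialized artifacts, a tie note when applicable, and the versioned
#' bundle used by the other run modes.
#'
#' @param run An `oml_run`.
#' @param output_dir Directory (created if missing).
#' @return Invisibly, `output_dir`.
#' @export
write_outputs <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$results_table, file.path(output_dir, "results_table.csv"))
  readr::write_csv(run$best$distances, file.path(output_dir, "model_selection.csv"))
  export_explanations(
    run$explanations, run$permimp, run$best$winner,
    output_dir
  )
  if (!is.null(run$selection_curve)) {
    readr::write_csv(
      tibble::as_tibble(run$selection_curve),
      file.path(output_dir, "feature_selection_curve.csv")
    )
  }
  best_dir <- file.path(output_dir, "best_model")
  dir.create(best_dir, showWarnings = FALSE)
  saveRDS(run$results[[run$best$winner]], file.path(best_dir, "model_result.rds"))
  readr::write_csv(
    dplyr::filter(run$results_table, .data$model == run$best$winner),
    file.path(best_dir, "metrics.csv")
  )
  if (!is.null(run$best$tie_note)) {
    writeLines(run$best$tie_note, file.path(output_dir, "best_model_tie_note.txt"))
  }
  bundle_dir <- file.path(output_dir, "bundle")
  dir.create(bundle_dir, showWarnings = FALSE)
  saveRDS(run$qmap, file.path(bundle_dir, "quantile_map.rds"))
  for (nm in names(run$results)) {
    saveRDS(run$results[[nm]], file.path(bundle_dir, paste0("model_", nm, ".rds")))
  }
  saveRDS(run, file.path(bundle_dir, "run.rds"))
  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("omicsml")),
      seed = run$config$seed,
      config_hash = rlang::hash(unclass(run$config)),
      models = names(run$results),
      best_model = run$best$winner,
      n_features = length(run$features),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    ),
    file.path(bundle_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  if (length(run$config$plots)) {
    render_plots(run, run$config$plots, file.path(output_dir, "plots"))
  }
  invisible(output_dir)
}

#' Load a persisted training run
#'
#' @param output_dir A directory written by [write_outputs()] (or by
#'   [run_training()] with `output_dir` set).
#' @return The `oml_run`.
#' @export
load_run <- function(output_dir) {
  path <- file.path(output_dir, "bundle", "run.rds")
  if (!file.exists(path)) {
    stop("no persisted training bundle under '", output_dir,
      "'; run training mode first",
      call. = FALSE
    )
  }
  readRDS(path)
}

# apply the persisted transforms to a new table, returning the model matrix
replay_transforms <- function(run, table) {
  table <- as_feature_table(table)
  std <- apply_quantile_map(run$qmap, table)
  m <- ft_matrix(std)
  missing <- setdiff(run$features, colnames(m))
  if (length(missing)) {
    stop("new data lacks selected feature(s): ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  m[, run$features, drop = FALSE]
}

#' Prediction mode: score new, unlabelled data with the best model
#'
#' Applies the persisted quantile map and feature selection, then the best
#' model; also exports Shapley explanations for the new samples.
#'
#' @param run An `oml_run` or a path to a persisted run directory.
#' @param table Feature table of new samples (or a CSV path).
#' @param output_dir Optional directory for `predictions.csv` and
#'   explanation CSVs.
#' @return A tibble of per-sample predictions (class probabilities included
#'   for classification).
#' @export
run_prediction <- function(run, table, output_dir = NULL) {
  if (is.character(run)) run <- load_run(run)
  if (is.character(table)) table <- read_feature_table(table)
  X <- replay_transforms(run, table)
  best <- run$results[[run$best$winner]]
  out <- predict(best$model, X)
  preds <- tibble::tibble(sample_id = rownames(X), prediction = out$pred)
  if (!is.null(out$prob)) {
    preds <- dplyr::bind_cols(
      preds,
      tibble::as_tibble(as.data.frame(out$prob, check.names = FALSE))
    )
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(preds, file.path(output_dir, "predictions.csv"))
    expl <- shapley_explanations(best$model, X,
      top_n = run$config$explanations$top_n,
      background = run$data$X_train,
      seed = derive_seed(run$config$seed, 6)
    )
    export_explanations(expl, NULL, run$best$winner, output_dir)
  }
  preds
}

#' Holdout mode: evaluate persisted models on a new labelled dataset
#'
#' @param run An `oml_run` or a path to a persisted run directory.
#' @param table Feature table (or CSV path) of holdout samples.
#' @param metadata Metadata tibble (or CSV path) with the target column.
#' @param output_dir Optional directory for `holdout_metrics.csv`.
#' @return A tibble: one row per model and metric on the holdout data.
#' @export
run_holdout <- function(run, table, metadata, output_dir = NULL) {
  if (is.character(run)) run <- load_run(run)
  if (is.character(table)) table <- read_feature_table(table)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  target <- extract_target(metadata, run$config$target_column, run$config$problem_type)
  aligned <- align_samples(table, target)
  X <- replay_transforms(run, aligned$table)
  y <- aligned$target$target
  if (!is.null(run$y_levels)) y <- factor(as.character(y), levels = run$y_levels)
  panel <- metric_panel(run$config$problem_type)
  out <- purrr::map_dfr(run$results, function(res) {
    pr <- predict(res$model, X)
    vals <- vapply(panel, function(nm) {
      tryCatch(compute_metric(nm, y, pr$pred, pr$prob), error = function(e) NA_real_)
    }, 0)
    tibble::tibble(model = res$name, metric = panel, holdout = unname(vals))
  })
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out, file.path(output_dir, "holdout_metrics.csv"))
  }
  out
}

#' Plotting mode: regenerate figures from a persisted run
#'
#' @param run An `oml_run` or a path to a persisted run directory.
#' @param plots Plot names (see [render_plots()]); defaults to the config's
#'   `plots` list.
#' @param output_dir Directory for images and companion CSVs.
#' @return Invisibly, the files written.
#' @export
run_plotting <- function(run, plots = NULL, output_dir) {
  if (is.character(run)) run <- load_run(run)
  plots <- plots %||% run$config$plots
  render_plots(run, plots, output_dir)
}
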