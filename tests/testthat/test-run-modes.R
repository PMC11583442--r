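# A single small training run shared across the mode tests.
make_small_run <- function(out_dir = NULL, seed = 42) {
  gen <- make_classification_table(n = 70, p = 20, n_informative = 5, effect = 2.5, seed = 71)
  cfg <- quietly(parse_config(list(
    data_path = "mem", metadata_path = "mem", target_column = "target",
    problem_type = "classification", models = c("rf", "knn"),
    hyper_tuning = "none", seed = seed,
    feature_selection = list(k = 8)
  )))
  list(
    gen = gen,
    run = quietly(run_training(cfg, out_dir, table = gen$table, target = gen$target))
  )
}

test_that("training persists the contracted artifact set", {
  out <- withr::local_tempdir()
  sr <- make_small_run(out)
  files <- list.files(out, recursive = TRUE)
  expect_true("results_table.csv" %in% files)
  expect_true(any(startsWith(files, "best_model/")))
  expect_true(any(grepl("^shapley_values_all_", files)))
  expect_true(any(grepl("^permutimp_TopFeatures_info_", files)))
  expect_true("bundle/manifest.json" %in% files)

  # results table: one row per model and metric
  rt <- readr::read_csv(file.path(out, "results_table.csv"), show_col_types = FALSE)
  expect_setequal(unique(rt$model), c("rf", "knn"))
  expect_identical(nrow(rt), 2L * length(metric_panel("classification")))

  manifest <- jsonlite::fromJSON(file.path(out, "bundle", "manifest.json"))
  expect_identical(manifest$seed, 42L)
  expect_identical(manifest$best_model, sr$run$best$winner)
})

test_that("prediction mode replays the persisted pipeline exactly", {
  out <- withr::local_tempdir()
  sr <- make_small_run(out)
  run <- sr$run

  # feed back 10 raw input rows: predictions must equal applying the
  # persisted transforms + best model manually
  newdata <- sr$gen$table[6:15, ]
  preds <- quietly(run_prediction(out, newdata))
  X_manual <- ft_matrix(
    apply_quantile_map(run$qmap, newdata)
  )[, run$features, drop = FALSE]
  manual <- predict(run$results[[run$best$winner]]$model, X_manual)
  expect_identical(preds$prediction, manual$pred)
  expect_equal(as.matrix(preds[, levels(manual$pred)]), manual$prob, ignore_attr = TRUE)

  # artifacts on disk
  pout <- withr::local_tempdir()
  quietly(run_prediction(out, newdata, output_dir = pout))
  expect_true("predictions.csv" %in% list.files(pout))
  expect_true(any(grepl("^shapley_values_all_", list.files(pout))))
})

test_that("holdout mode on relabelled training rows reproduces train metrics", {
  out <- withr::local_tempdir()
  sr <- make_small_run(out)
  run <- sr$run

  # the training partition, re-presented as an external labelled dataset
  train_ids <- run$split$train$table$sample_id
  table_ho <- dplyr::filter(sr$gen$table, sample_id %in% train_ids)
  meta_ho <- dplyr::filter(sr$gen$target, sample_id %in% train_ids)
  ho <- quietly(run_holdout(out, table_ho, meta_ho))

  for (nm in names(run$results)) {
    stored <- run$results[[nm]]$train_metrics
    got <- dplyr::filter(ho, .data$model == nm)
    for (metric in c("accuracy", "f1", "precision")) {
      expect_equal(
        got$holdout[got$metric == metric],
        unname(stored[[metric]]),
        tolerance = 1e-12,
        label = paste(nm, metric, "holdout replay")
      )
    }
  }
  expect_error(quietly(run_holdout(withr::local_tempdir(), table_ho, meta_ho)), "bundle")
})

test_that("no leakage: test rows never influence fitted transforms or features", {
  gen <- make_classification_table(n = 70, p = 20, n_informative = 5, effect = 2.5, seed = 71)
  cfg <- quietly(parse_config(list(
    data_path = "mem", metadata_path = "mem", target_column = "target",
    problem_type = "classification", models = "knn", hyper_tuning = "none",
    seed = 11, feature_selection = list(k = 8)
  )))
  run1 <- quietly(run_training(cfg, table = gen$table, target = gen$target))

  # perturb exactly the rows that land in the test partition
  test_ids <- run1$split$test$table$sample_id
  tampered <- gen$table
  idx <- tampered$sample_id %in% test_ids
  tampered[idx, -1] <- tampered[idx, -1] * 5 + 3
  run2 <- quietly(run_training(cfg, table = tampered, target = gen$target))

  expect_identical(run2$split$test$table$sample_id, test_ids)
  expect_identical(run1$qmap$grids, run2$qmap$grids) # transform untouched
  expect_identical(run1$features, run2$features) # selection untouched
})

test_that("plot mode regenerates figures from the persisted bundle", {
  out <- withr::local_tempdir()
  make_small_run(out)
  pdir <- withr::local_tempdir()
  files <- run_plotting(out, plots = c("cv_box", "confusion"), output_dir = pdir)
  expect_setequal(
    list.files(pdir),
    c("cv_box.png", "cv_box.csv", "confusion.png", "confusion.csv")
  )
})

test_that("balancing is applied to the training partition only", {
  gen <- make_classification_table(n = 75, p = 10, n_informative = 3, effect = 2, seed = 73)
  # unbalance: drop most of class 2
  keep <- c(
    which(gen$target$target == "class_1"),
    which(gen$target$target == "class_2")[1:12]
  )
  tab <- gen$table[keep, ]
  tgt <- gen$target[keep, ]
  cfg <- quietly(parse_config(list(
    data_path = "mem", metadata_path = "mem", target_column = "target",
    problem_type = "classification", models = "rf", hyper_tuning = "none",
    balancing = "oversample", seed = 5
  )))
  run <- quietly(run_training(cfg, table = tab, target = tgt))
  # test partition keeps its natural (imbalanced) class ratio
  test_counts <- table(run$data$y_test)
  expect_false(test_counts[["class_1"]] == test_counts[["class_2"]])
  # and evaluation rows are the untouched split, not resampled copies
  expect_identical(nrow(run$data$X_train), nrow(run$split$train$table))
})
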