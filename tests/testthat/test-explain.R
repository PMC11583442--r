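# Attribution correctness: exact tree-path Shapley values are checked
# against brute-force subset enumeration (small trees), the additivity
# axiom, and hand-computed two-player games; permutation importance against
# closed-form expectations on rule models.

test_that("tree attributions equal brute-force Shapley enumeration", {
  set.seed(43)
  for (i in 1:10) {
    n <- 50
    p <- 4
    X <- matrix(rnorm(n * p), n, p)
    y <- 2 * X[, 1] + (X[, 2] > 0) + rnorm(n, 0, 0.3)
    tree <- omicsml:::cpp_build_tree(X, y, integer(n), 0L, rep(1, n), 5L, 2L, p, i)
    Xq <- matrix(rnorm(2 * p), 2, p)
    phi <- omicsml:::cpp_tree_shap(tree, Xq, 0L)
    for (r in 1:2) {
      expect_equal(unname(phi[r, ]), tree_shap_brute(tree, Xq[r, ], p), tolerance = 1e-9)
    }
    # additivity: base + sum(phi) = prediction
    pred <- omicsml:::cpp_predict_tree(tree, Xq)[, 1]
    expect_equal(attr(phi, "base") + rowSums(phi), pred, tolerance = 1e-9)
  }
})

test_that("a depth-1 split is the hand-computed two-player game", {
  # stump on feature 1: leaves a (cover 6, value 1) and b (cover 4, value 5)
  tree <- list(
    feature = c(0L, -1L, -1L), threshold = c(0.5, 0, 0),
    left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
    cover = c(10, 6, 4), value = matrix(c(0, 1, 5), ncol = 1)
  )
  x <- matrix(c(0.2, 99), 1, 2) # goes left -> f(x) = 1
  phi <- omicsml:::cpp_tree_shap(tree, x, 0L)
  base <- (6 * 1 + 4 * 5) / 10
  # only feature 1 plays: phi1 = f(x) - E[f], phi2 = 0 in both orderings
  expect_equal(unname(phi[1, ]), c(1 - base, 0))
  expect_equal(attr(phi, "base"), base)
})

test_that("model-level explanations satisfy additivity on the raw output", {
  gen <- make_classification_table(n = 80, p = 6, n_informative = 3, effect = 2, seed = 47)
  X <- table_matrix(gen$table)
  y <- gen$target$target
  Xq <- X[1:15, ]

  for (nm in c("rf", "gradient_boosted_trees", "adaboost", "lightgbm_style")) {
    spec <- model_registry("classification")[[nm]]
    model <- spec$fit(X, y, spec$default, seed = 7)
    expl <- shapley_explanations(model, Xq)
    expect_identical(expl$method, "exact_tree_path")
    raw <- predict(model, Xq)$raw
    for (cls in names(expl$attributions)) {
      recon <- expl$base_values[[cls]] + rowSums(expl$attributions[[cls]])
      expect_equal(recon, unname(raw[, cls]),
        tolerance = 1e-6,
        label = paste(nm, cls, "additivity")
      )
    }
  }

  # regression forest: base + sum = predicted value
  genr <- make_regression_table(n = 80, p = 6, n_informative = 3, r2_target = 0.9, seed = 48)
  Xr <- table_matrix(genr$table)
  rf <- model_registry("regression")[["rf"]]
  mr <- rf$fit(Xr, genr$target$target, rf$default, seed = 7)
  er <- shapley_explanations(mr, Xr[1:10, ])
  expect_equal(
    er$base_values[["value"]] + rowSums(er$attributions[["value"]]),
    predict(mr, Xr[1:10, ])$pred,
    tolerance = 1e-6
  )
})

test_that("constant models attribute nothing", {
  # a forest grown on a constant target is a constant model
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("f", 1:3)))
  spec <- model_registry("regression")[["rf"]]
  model <- spec$fit(X, rep(2.5, 40), spec$default, seed = 1)
  expl <- shapley_explanations(model, X[1:5, ])
  expect_equal(max(abs(expl$attributions[["value"]])), 0)
  expect_equal(unname(expl$base_values[["value"]]), 2.5)
})

test_that("the sampling approximation recovers additive structure for knn", {
  set.seed(51)
  X <- matrix(runif(60 * 3), 60, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- 4 * X[, 1] + 0 * X[, 2] + rnorm(60, 0, 0.05)
  spec <- model_registry("regression")[["knn"]]
  model <- spec$fit(X, y, list(k = 3), seed = 1)
  expl <- shapley_explanations(model, X[1:8, ], background = X, seed = 9)
  expect_identical(expl$method, "permutation_sampling")
  # the driving feature dominates the ranking
  expect_identical(expl$ranking$feature[1], "f1")
  # determinism of the seeded approximation
  expl2 <- shapley_explanations(model, X[1:8, ], background = X, seed = 9)
  expect_identical(expl$attributions, expl2$attributions)
})

test_that("permutation importance isolates predictive features", {
  set.seed(53)
  n <- 80
  X <- cbind(
    signal = rep(c(0, 1), each = n / 2),
    noise = rnorm(n)
  )
  y <- factor(ifelse(X[, "signal"] == 1, "pos", "neg"), levels = c("neg", "pos"))
  spec <- model_registry("classification")[["rf"]]
  model <- spec$fit(X, y, list(n_trees = 25), seed = 3)

  imp <- permutation_importance(model, X, y, "accuracy", repeats = 5, seed = 5)
  # single perfectly predictive feature: baseline = 1; a permuted signal
  # column agrees with the truth about half the time -> importance near 0.5
  expect_gt(imp$importance[imp$feature == "signal"], 0.3)
  expect_lt(abs(imp$importance[imp$feature == "noise"]), 0.05)

  # identical seeds give identical importances
  imp2 <- permutation_importance(model, X, y, "accuracy", repeats = 5, seed = 5)
  expect_identical(imp, imp2)

  # error-type metrics keep the larger-is-more-important convention
  genr <- make_regression_table(n = 60, p = 4, n_informative = 1, r2_target = 0.9, seed = 54)
  Xr <- table_matrix(genr$table)
  rfspec <- model_registry("regression")[["rf"]]
  mr <- rfspec$fit(Xr, genr$target$target, list(n_trees = 25), seed = 1)
  impr <- permutation_importance(mr, Xr, genr$target$target, "mae", repeats = 3, seed = 2)
  expect_identical(
    impr$feature[which.max(impr$importance)],
    genr$truth$informative
  )
})

test_that("explanation exports use the exact file-name templates", {
  gen <- make_classification_table(
    n = 45, p = 5, n_informative = 2, effect = 2,
    n_classes = 3, seed = 55
  )
  X <- table_matrix(gen$table)
  spec <- model_registry("classification")[["rf"]]
  model <- spec$fit(X, gen$target$target, list(n_trees = 25), seed = 1)
  expl <- shapley_explanations(model, X[1:9, ], top_n = 4)
  imp <- permutation_importance(model, X, gen$target$target, "f1", repeats = 2, seed = 1)

  out <- withr::local_tempdir()
  export_explanations(expl, imp, "rf", out)
  files <- list.files(out)
  expect_true("permutimp_TopFeatures_info_rf.csv" %in% files)
  # one Shapley CSV per class, class name embedded
  for (cls in levels(gen$target$target)) {
    expect_true(paste0("shapley_values_all_rf_", cls, ".csv") %in% files)
  }
  # CSV re-read equals the in-memory matrix
  back <- readr::read_csv(
    file.path(out, paste0("shapley_values_all_rf_", levels(gen$target$target)[1], ".csv")),
    show_col_types = FALSE
  )
  expect_equal(
    as.matrix(back[, -1]),
    expl$attributions[[1]],
    ignore_attr = TRUE, tolerance = 1e-12
  )

  # regression run -> a single Shapley CSV, no class suffix
  genr <- make_regression_table(n = 40, p = 4, n_informative = 2, seed = 56)
  rfr <- model_registry("regression")[["rf"]]
  mreg <- rfr$fit(table_matrix(genr$table), genr$target$target, list(n_trees = 10), seed = 1)
  explr <- shapley_explanations(mreg, table_matrix(genr$table)[1:5, ])
  out2 <- withr::local_tempdir()
  export_explanations(explr, NULL, "rf", out2)
  expect_identical(list.files(out2), "shapley_values_all_rf.csv")

  # ranking length respects top_n
  expect_identical(nrow(expl$ranking), 4L)
})
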