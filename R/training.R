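#' Cross-validation and hyperparameter tuning
#'
#' Hyperparameters are tuned on the training partition by grid search,
#' seeded random search (default budget 20 draws), or not at all; every
#' candidate configuration is scored by k-fold cross-validation (stratified
#' for classification, 5 folds by default) with the configured metric, the
#' winner is refit on the full training partition, and its per-fold scores
#' are retained for the CV box plots.
#'
#' @name model_training
NULL

make_folds <- function(y, n_folds, seed) {
  n <- length(y)
  rng <- local_rng(seed)
  fold <- integer(n)
  if (is.factor(y)) {
    for (lv in levels(y)) {
      idx <- rng$sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    fold[rng$sample_int(n)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

#' Cross-validate one model configuration
#'
#' @param spec A registry entry from [model_registry()].
#' @param X Training matrix.
#' @param y Training target.
#' @param params Hyperparameter list.
#' @param scoring Metric name.
#' @param n_folds Number of folds.
#' @param seed Seed controlling folds and per-fold model fits.
#' @return Numeric vector of per-fold scores.
#' @export
cross_validate <- function(spec, X, y, params, scoring, n_folds = 5, seed = 42) {
  fold <- make_folds(y, n_folds, derive_seed(seed, 7))
  vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    model <- spec$fit(X[tr, , drop = FALSE], y[tr], params, derive_seed(seed, 100 + f))
    out <- predict(model, X[!tr, , drop = FALSE])
    compute_metric(scoring, y[!tr], out$pred, out$prob)
  }, 0)
}

expand_param_grid <- function(grid) {
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Tune and fit one registry model
#'
#' @param spec Registry entry.
#' @param X Training matrix (standardised/selected/balanced upstream).
#' @param y Training target.
#' @param search `"random"`, `"grid"`, or `"none"`.
#' @param scoring Metric name; must match the problem type.
#' @param n_folds CV folds (default 5).
#' @param seed Integer seed; identical seeds replay identical searches.
#' @param n_iter Random-search budget (default 20 draws).
#' @return An `oml_model_result`: model name, chosen hyperparameters,
#'   per-fold CV scores of the winner, and the refit model.
#' @export
tune_and_fit <- function(spec, X, y, search = c("random", "grid", "none"),
                         scoring, n_folds = 5, seed = 42, n_iter = 20) {
  search <- match.arg(search)
  info <- METRIC_INFO[[scoring]]
  if (is.null(info)) stop("unknown metric '", scoring, "'", call. = FALSE)
  expected <- if (is.factor(y)) "classification" else "regression"
  if (info$type != expected) {
    stop("metric '", scoring, "' is incompatible with a ", expected, " task",
      call. = FALSE
    )
  }
  candidates <- switch(search,
    none = list(spec$default),
    grid = lapply(
      expand_param_grid(spec$grid),
      function(g) merge_params(spec$default, g)
    ),
    random = {
      rng <- local_rng(derive_seed(seed, 11))
      c(list(spec$default), lapply(seq_len(n_iter - 1), function(i) {
        merge_params(spec$default, spec$sample_params(rng))
      }))
    }
  )
  cv_scores <- lapply(
    candidates,
    function(prm) cross_validate(spec, X, y, prm, scoring, n_folds, seed)
  )
  means <- vapply(cv_scores, mean, 0)
  best <- if (metric_orientation(scoring) == "score") which.max(means) else which.min(means)
  model <- spec$fit(X, y, candidates[[best]], derive_seed(seed, 999))
  structure(
    list(
      name = spec$name, params = candidates[[best]],
      cv_scores = cv_scores[[best]], scoring = scoring,
      search = search, n_candidates = length(candidates),
      model = model
    ),
    class = "oml_model_result"
  )
}

#' Evaluate a tuned model on both partitions
#'
#' Fills the train and test metric panels and caches predictions for
#' plotting and explanation.
#'
#' @param result An `oml_model_result` from [tune_and_fit()].
#' @param X_train,y_train,X_test,y_test The transformed partitions.
#' @param panel Metric names; defaults to the full panel for the problem type.
#' @return The completed `oml_model_result` (metrics + cached predictions).
#' @export
evaluate_on_split <- function(result, X_train, y_train, X_test, y_test,
                              panel = NULL) {
  cls <- is.factor(y_train)
  panel <- panel %||% metric_panel(if (cls) "classification" else "regression")
  panel <- union(panel, result$scoring)
  safe_panel <- function(y, out) {
    vapply(panel, function(nm) {
      tryCatch(compute_metric(nm, y, out$pred, out$prob),
        error = function(e) NA_real_
      )
    }, 0)
  }
  out_tr <- predict(result$model, X_train)
  out_te <- predict(result$model, X_test)
  result$train_metrics <- safe_panel(y_train, out_tr)
  result$test_metrics <- safe_panel(y_test, out_te)
  result$predictions <- list(train = out_tr, test = out_te)
  result
}

#' @export
print.oml_model_result <- function(x, ...) {
  cat(
    "<oml_model_result>", x$name, "| cv", x$scoring, "=",
    signif(mean(x$cv_scores), 4)
  )
  if (!is.null(x$test_metrics)) {
    cat(" | test", x$scoring, "=", signif(x$test_metrics[[x$scoring]], 4))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a tuned model result
#'
#' One row per metric with train/CV/test values, broom-style.
#'
#' @param x An `oml_model_result`.
#' @param ... Unused.
#' @return A tibble with columns `model`, `metric`, `train`, `cv_mean`,
#'   `cv_sd`, `test`.
#' @method tidy oml_model_result
#' @export
tidy.oml_model_result <- function(x, ...) {
  metrics <- names(x$train_metrics)
  tibble::tibble(
    model = x$name,
    metric = metrics,
    train = unname(x$train_metrics[metrics]),
    cv_mean = ifelse(metrics == x$scoring, mean(x$cv_scores), NA_real_),
    cv_sd = ifelse(metrics == x$scoring, stats::sd(x$cv_scores), NA_real_),
    test = unname(x$test_metrics[metrics])
  )
}

#' Glance at a tuned model result
#'
#' @param x An `oml_model_result`.
#' @param ... Unused.
#' @return A one-row tibble: model, scoring metric, train/cv/test values.
#' @method glance oml_model_result
#' @export
glance.oml_model_result <- function(x, ...) {
  tibble::tibble(
    model = x$name,
    scoring = x$scoring,
    train = unname(x$train_metrics[[x$scoring]]),
    cv_mean = mean(x$cv_scores),
    cv_sd = stats::sd(x$cv_scores),
    test = unname(x$test_metrics[[x$scoring]]),
    n_candidates = x$n_candidates
  )
}
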