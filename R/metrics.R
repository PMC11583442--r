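#' Evaluation metrics
#'
#' The metric panel covers the standard classification metrics (accuracy,
#' precision, F1, one-vs-rest ROC AUC) and regression metrics (MSE, MAE,
#' MAPE, R-squared). Each metric carries an *orientation* -- score-type
#' (higher is better, bounded above by 1) or error-type (lower is better,
#' non-negative) -- used by automated-k evaluation and best-model selection.
#' For binary targets, precision and F1 refer to the positive class, defined
#' as the second factor level; for more than two classes they are averaged
#' weighted by class support.
#'
#' @name metrics
NULL

METRIC_INFO <- list(
  accuracy  = list(orientation = "score", type = "classification", needs_prob = FALSE),
  precision = list(orientation = "score", type = "classification", needs_prob = FALSE),
  f1        = list(orientation = "score", type = "classification", needs_prob = FALSE),
  auc       = list(orientation = "score", type = "classification", needs_prob = TRUE),
  mse       = list(orientation = "error", type = "regression", needs_prob = FALSE),
  mae       = list(orientation = "error", type = "regression", needs_prob = FALSE),
  mape      = list(orientation = "error", type = "regression", needs_prob = FALSE),
  r2        = list(orientation = "score", type = "regression", needs_prob = FALSE)
)

#' Orientation of a metric
#'
#' @param name Metric name.
#' @return `"score"` (higher better) or `"error"` (lower better).
#' @export
metric_orientation <- function(name) {
  info <- METRIC_INFO[[name]]
  if (is.null(info)) stop("unknown metric '", name, "'", call. = FALSE)
  info$orientation
}

#' Metric panel for a problem type
#'
#' @param problem_type `"classification"` or `"regression"`.
#' @return Character vector of metric names.
#' @export
metric_panel <- function(problem_type) {
  names(Filter(function(i) i$type == problem_type, METRIC_INFO))
}

prf_counts <- function(y_true, y_pred, lv) {
  tp <- sum(y_true == lv & y_pred == lv)
  fp <- sum(y_true != lv & y_pred == lv)
  fn <- sum(y_true == lv & y_pred != lv)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1, support = sum(y_true == lv))
}

# rank-based AUC of scores for the positive class
binary_auc <- function(is_pos, score) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) stop("AUC needs both classes present", call. = FALSE)
  r <- rank(score, ties.method = "average")
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Compute one evaluation metric
#'
#' @param name Metric name (see [metric_panel()]).
#' @param y_true Observed labels (factor) or numeric values.
#' @param y_pred Predicted labels or numeric values.
#' @param prob For `"auc"`: matrix of class probabilities, columns named by
#'   class level.
#' @return A single numeric value.
#' @export
compute_metric <- function(name, y_true, y_pred, prob = NULL) {
  info <- METRIC_INFO[[name]]
  if (is.null(info)) stop("unknown metric '", name, "'", call. = FALSE)
  if (info$type == "classification") {
    y_true <- factor(y_true)
    lv <- levels(y_true)
    if (name == "auc") {
      if (is.null(prob)) stop("AUC requires class probability scores", call. = FALSE)
      present <- lv[lv %in% unique(as.character(y_true))]
      if (length(present) < 2) stop("AUC undefined with a single class present", call. = FALSE)
      # one-vs-rest, averaged over present classes weighted by support
      aucs <- vapply(present, function(l) binary_auc(y_true == l, prob[, l]), 0)
      w <- vapply(present, function(l) sum(y_true == l), 0)
      return(sum(aucs * w) / sum(w))
    }
    y_pred <- factor(as.character(y_pred), levels = lv)
    if (name == "accuracy") {
      return(mean(as.character(y_true) == as.character(y_pred)))
    }
    stats_by_class <- t(vapply(lv, function(l) prf_counts(y_true, y_pred, l), numeric(4)))
    if (length(lv) == 2) { # binary: positive class = second level
      return(unname(stats_by_class[2, name]))
    }
    w <- stats_by_class[, "support"]
    return(sum(stats_by_class[, name] * w) / sum(w))
  }
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  switch(name,
    mse = mean((y_true - y_pred)^2),
    mae = mean(abs(y_true - y_pred)),
    mape = {
      if (any(y_true == 0)) stop("MAPE undefined when any observed value is 0", call. = FALSE)
      100 * mean(abs((y_true - y_pred) / y_true))
    },
    r2 = {
      ss_tot <- sum((y_true - mean(y_true))^2)
      if (ss_tot == 0) stop("R² undefined for a constant target", call. = FALSE)
      1 - sum((y_true - y_pred)^2) / ss_tot
    }
  )
}

#' Compute a panel of metrics from cached predictions
#'
#' @param panel Character vector of metric names.
#' @param y_true Observed target.
#' @param y_pred Predicted target.
#' @param prob Class-probability matrix (classification only).
#' @return Named numeric vector.
#' @export
compute_metric_panel <- function(panel, y_true, y_pred, prob = NULL) {
  vapply(panel, function(nm) compute_metric(nm, y_true, y_pred, prob), 0)
}
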