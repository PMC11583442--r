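#' Univariate feature selection with automated k
#'
#' Selection runs on the (standardised) training partition only. Variance
#' thresholding drops constant/near-constant columns first; features are then
#' scored univariately (one-way ANOVA F for classification, univariate
#' linear-regression F for regression) and the k best kept. k may be fixed or
#' searched automatically: candidate ks are log-spaced between a minimum and
#' maximum, each candidate is scored by cross-validating a default
#' random-forest model on the k best features, and the final k is the largest
#' member of the best-performing, most stable window of three consecutive
#' candidates. A lone spike whose neighbours perform poorly (a "V" shape)
#' is deliberately not chosen.
#'
#' @name feature_select
NULL

#' Remove constant and near-constant features
#'
#' Keeps a feature iff its population variance is strictly greater than
#' `threshold` (default 0: drop exact constants).
#'
#' @param table Feature table.
#' @param threshold Non-negative variance threshold.
#' @return List with `table` (filtered) and `removed` (feature IDs).
#' @export
variance_filter <- function(table, threshold = 0) {
  table <- as_feature_table(table)
  stopifnot(threshold >= 0)
  m <- ft_matrix(table)
  v <- colMeans(m^2) - colMeans(m)^2 # population variance
  v <- pmax(v, 0)
  keep <- v > threshold
  if (!any(keep)) stop("no features remain after variance filtering", call. = FALSE)
  list(
    table = table[, c(TRUE, keep), drop = FALSE],
    removed = colnames(m)[!keep]
  )
}

#' ANOVA F scores of features against class labels
#'
#' Per feature, the one-way ANOVA F statistic: between-class mean square over
#' within-class mean square. A feature with zero within-class variance but
#' class-separated means scores `Inf` (ranked above all finite scores); a
#' feature constant everywhere scores 0 with a warning.
#'
#' @param X Numeric matrix (samples x features).
#' @param y Factor of class labels (>= 2 classes).
#' @return Named numeric vector of F scores.
#' @export
f_classif_scores <- function(X, y) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  n <- nrow(X)
  G <- nlevels(y)
  grand <- colMeans(X)
  ss_between <- numeric(ncol(X))
  ss_within <- numeric(ncol(X))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    mu_g <- colMeans(X[idx, , drop = FALSE])
    ss_between <- ss_between + length(idx) * (mu_g - grand)^2
    ss_within <- ss_within +
      colSums((X[idx, , drop = FALSE] - matrix(mu_g, length(idx), ncol(X), byrow = TRUE))^2)
  }
  msb <- ss_between / (G - 1)
  msw <- ss_within / (n - G)
  f <- msb / msw
  degenerate <- msw == 0 & msb == 0
  if (any(degenerate)) {
    warning("constant feature(s) score F = 0: ",
      paste(utils::head(colnames(X)[degenerate], 5), collapse = ", "),
      call. = FALSE
    )
    f[degenerate] <- 0
  }
  f[msw == 0 & msb > 0] <- Inf
  stats::setNames(f, colnames(X))
}

#' Univariate regression F scores of features against a numeric target
#'
#' Per feature, the F statistic of the univariate linear regression of the
#' target on that feature: `F = r^2 / (1 - r^2) * (n - 2)` with `r` the
#' Pearson correlation. A perfectly correlated feature scores `Inf`.
#'
#' @param X Numeric matrix (samples x features).
#' @param y Numeric target.
#' @return Named numeric vector of F scores.
#' @export
f_regression_scores <- function(X, y) {
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  sx <- sqrt(colSums(xc^2))
  sy <- sqrt(sum(yc^2))
  r <- as.numeric(crossprod(xc, yc)) / (sx * sy)
  r[sx == 0 | sy == 0] <- 0
  r2 <- pmin(r^2, 1)
  f <- r2 / (1 - r2) * (n - 2)
  f[r2 >= 1] <- Inf
  stats::setNames(f, colnames(X))
}

#' Select the k best-scoring features
#'
#' Ties are broken by input feature order (first wins); infinite scores rank
#' above all finite ones.
#'
#' @param scores Named score vector (as from [f_classif_scores()]).
#' @param k Number of features to keep, `1 <= k <= length(scores)`.
#' @return Character vector of the k selected feature IDs, in input order.
#' @export
select_k_best <- function(scores, k) {
  p <- length(scores)
  if (k < 1 || k > p) stop("k must be in [1, ", p, "]", call. = FALSE)
  ord <- order(-scores, seq_len(p)) # stable: ties by input order
  sort(ord[seq_len(k)]) |> (\(i) names(scores)[i])()
}

#' Log-spaced candidate feature counts
#'
#' @param auto_min,auto_max Bounds (inclusive); `auto_min < auto_max`.
#' @param n_candidates Number of points before rounding/deduplication.
#' @return Ascending unique integer candidates including both endpoints.
#' @export
candidate_ks <- function(auto_min, auto_max, n_candidates = 10) {
  stopifnot(auto_min >= 1, auto_min < auto_max)
  ks <- exp(seq(log(auto_min), log(auto_max), length.out = n_candidates))
  sort(unique(c(auto_min, round(ks), auto_max)))
}

#' Choose the best stable window of three consecutive candidate scores
#'
#' For every window of three consecutive candidates, computes the mean `m`
#' and (sample) standard deviation `s` of the scores, then picks the window
#' maximising `m - s` for score-type metrics or minimising `m + s` for
#' error-type metrics. Exact ties go to the window with the better mean, then
#' to the window with the larger maximal k. Returns the largest k of the
#' chosen window.
#'
#' @param ks Ascending candidate ks (>= 3).
#' @param scores Mean CV score per candidate.
#' @param orientation `"score"` (higher better) or `"error"` (lower better).
#' @return List: `k` (chosen), `window` (indices), `m`, `s`.
#' @export
pick_stable_window <- function(ks, scores, orientation = c("score", "error")) {
  orientation <- match.arg(orientation)
  stopifnot(length(ks) == length(scores), length(ks) >= 3)
  n_win <- length(ks) - 2L
  m <- vapply(seq_len(n_win), function(i) mean(scores[i:(i + 2)]), 0)
  s <- vapply(seq_len(n_win), function(i) stats::sd(scores[i:(i + 2)]), 0)
  crit <- if (orientation == "score") m - s else -(m + s)
  best <- max(crit)
  cand <- which(crit >= best - 1e-12)
  if (length(cand) > 1) { # ties: larger mean, then larger max k
    mm <- if (orientation == "score") m[cand] else -m[cand]
    cand <- cand[mm >= max(mm) - 1e-12]
    cand <- max(cand)
  }
  i <- cand
  list(k = ks[i + 2L], window = i:(i + 2L), m = m[i], s = s[i])
}

#' Automated search for the number of features
#'
#' Evaluates each candidate k by selecting the k best univariate features and
#' cross-validating a fixed-seed default random forest (100 trees, 5-fold) on
#' them with the configured scoring metric, then applies the stable-window
#' rule of [pick_stable_window()].
#'
#' @param X Numeric training matrix (samples x features).
#' @param y Training target (factor or numeric).
#' @param auto_min,auto_max Candidate bounds; at least 3 unique candidates
#'   must be realisable.
#' @param scoring Metric name (see [compute_metric()]); default `"f1"` for
#'   classification, `"mae"` for regression.
#' @param seed Integer seed for CV folds and forests.
#' @param n_folds Cross-validation folds (default 5).
#' @param n_candidates Log-spaced candidates before deduplication.
#' @return List with `k` and `curve`, an `oml_selection_curve` tibble
#'   (columns `k`, `score`) with the chosen window in attributes.
#' @export
auto_select_k <- function(X, y, auto_min, auto_max,
                          scoring = NULL, seed = 42,
                          n_folds = 5, n_candidates = 10) {
  classification <- is.factor(y)
  if (is.null(scoring)) scoring <- if (classification) "f1" else "mae"
  if (auto_max > ncol(X)) stop("auto_max exceeds the number of features", call. = FALSE)
  ks <- candidate_ks(auto_min, auto_max, n_candidates)
  if (length(ks) < 3) stop("fewer than 3 unique candidate ks", call. = FALSE)
  scores <- if (classification) f_classif_scores(X, y) else f_regression_scores(X, y)
  spec <- model_registry(if (classification) "classification" else "regression")[["rf"]]
  curve_scores <- vapply(ks, function(k) {
    sel <- select_k_best(scores, k)
    cv <- cross_validate(
      spec, X[, sel, drop = FALSE], y, spec$default,
      scoring = scoring, n_folds = n_folds, seed = derive_seed(seed, 101)
    )
    mean(cv)
  }, 0)
  orientation <- metric_orientation(scoring)
  win <- pick_stable_window(ks, curve_scores, orientation)
  curve <- tibble::tibble(k = ks, score = curve_scores)
  attr(curve, "chosen_k") <- win$k
  attr(curve, "window") <- win$window
  attr(curve, "scoring") <- scoring
  class(curve) <- c("oml_selection_curve", class(curve))
  list(k = win$k, curve = curve)
}

#' Full feature-selection stage
#'
#' Variance filter, univariate scoring, then fixed-k or automated-k best-k
#' selection, per the run configuration. With `feature_selection = NULL` the
#' stage is the identity.
#'
#' @param train_table Standardised training feature table.
#' @param y Training target (factor or numeric).
#' @param fs `feature_selection` block of a run configuration (or `NULL`).
#' @param scoring Metric name used by the automated search.
#' @param seed Integer seed.
#' @return List: `features` (selected IDs), `curve` (or `NULL`),
#'   `variance_removed`.
#' @export
run_feature_selection <- function(train_table, y, fs, scoring = NULL, seed = 42) {
  train_table <- as_feature_table(train_table)
  if (is.null(fs)) {
    return(list(
      features = ft_features(train_table), curve = NULL,
      variance_removed = character()
    ))
  }
  vf <- variance_filter(train_table, fs$variance_threshold %||% 0)
  X <- ft_matrix(vf$table)
  k <- fs$k
  if (is.null(k)) {
    return(list(
      features = colnames(X), curve = NULL,
      variance_removed = vf$removed
    ))
  }
  if (identical(k, "auto")) {
    auto_max <- min(fs$auto_max %||% ncol(X), ncol(X))
    auto_min <- fs$auto_min %||% max(2L, min(10L, auto_max - 1L))
    res <- auto_select_k(X, y, auto_min, auto_max,
      scoring = scoring, seed = seed
    )
    scores <- if (is.factor(y)) f_classif_scores(X, y) else f_regression_scores(X, y)
    sel <- select_k_best(scores, res$k)
    return(list(features = sel, curve = res$curve, variance_removed = vf$removed))
  }
  k <- as.integer(k)
  if (k > ncol(X)) stop("k (", k, ") exceeds available features (", ncol(X), ")", call. = FALSE)
  scores <- if (is.factor(y)) f_classif_scores(X, y) else f_regression_scores(X, y)
  list(
    features = select_k_best(scores, k), curve = NULL,
    variance_removed = vf$removed
  )
}
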