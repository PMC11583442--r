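#' Model registry
#'
#' Five classical learners, each available as classifier and regressor, all
#' built on the package's compiled CART tree engine (plus k-nearest
#' neighbours): `rf` (random forest), `gradient_boosted_trees` (gradient
#' boosting: least-squares for regression, logistic/softmax for
#' classification), `adaboost` (SAMME for classification, AdaBoost.R2 for
#' regression), `knn`, and `lightgbm_style` (the same boosting engine with
#' histogram-binned split finding, the defining LightGBM trait). Every entry
#' carries default hyperparameters, a grid for grid search, and a sampler for
#' random search.
#'
#' @param problem_type `"classification"` or `"regression"`.
#' @param models Optional character vector restricting the registry.
#' @return Named list of model specs.
#' @export
model_registry <- function(problem_type = c("classification", "regression"),
                           models = NULL) {
  problem_type <- match.arg(problem_type)
  cls <- problem_type == "classification"
  reg <- list(
    rf = list(
      default = list(n_trees = 100, max_depth = 0, min_leaf = 1),
      grid = list(n_trees = c(100, 300), max_depth = c(0, 6, 12)),
      sample_params = function(rng) list(
        n_trees = rng$sample(c(100, 300, 500), 1),
        max_depth = rng$sample(c(0, 3, 6, 12, 20), 1),
        min_leaf = rng$sample(c(1, 3, 5), 1)
      ),
      fit = function(X, y, params, seed) fit_rf(X, y, params, seed)
    ),
    gradient_boosted_trees = list(
      default = list(n_rounds = 100, learning_rate = 0.1, max_depth = 3, min_leaf = 5),
      grid = list(learning_rate = c(0.3, 0.1, 0.03), max_depth = c(3, 6)),
      sample_params = function(rng) list(
        n_rounds = rng$sample(c(100, 300, 500), 1),
        learning_rate = rng$sample(c(0.3, 0.1, 0.03), 1),
        max_depth = rng$sample(c(2, 3, 6), 1),
        min_leaf = rng$sample(c(1, 5, 10), 1)
      ),
      fit = function(X, y, params, seed) fit_gbt(X, y, params, seed)
    ),
    adaboost = list(
      default = list(n_estimators = 50, max_depth = 3),
      grid = list(n_estimators = c(50, 100), max_depth = c(1, 3)),
      sample_params = function(rng) list(
        n_estimators = rng$sample(c(25, 50, 100, 200), 1),
        max_depth = rng$sample(c(1, 2, 3), 1)
      ),
      fit = function(X, y, params, seed) fit_adaboost(X, y, params, seed)
    ),
    knn = list(
      default = list(k = 5),
      grid = list(k = c(3, 5, 11, 21)),
      sample_params = function(rng) list(k = rng$sample(c(3, 5, 7, 11, 15, 21), 1)),
      fit = function(X, y, params, seed) fit_knn(X, y, params, seed)
    ),
    lightgbm_style = list(
      default = list(
        n_rounds = 100, learning_rate = 0.1, max_depth = 5,
        min_leaf = 5, max_bin = 63
      ),
      grid = list(learning_rate = c(0.1, 0.03), max_bin = c(15, 63)),
      sample_params = function(rng) list(
        n_rounds = rng$sample(c(100, 300, 500), 1),
        learning_rate = rng$sample(c(0.3, 0.1, 0.03), 1),
        max_depth = rng$sample(c(3, 5, 8), 1),
        min_leaf = rng$sample(c(1, 5, 10), 1),
        max_bin = rng$sample(c(15, 63, 255), 1)
      ),
      fit = function(X, y, params, seed) fit_binned_gbt(X, y, params, seed)
    )
  )
  for (nm in names(reg)) {
    reg[[nm]]$name <- nm
    reg[[nm]]$problem_type <- problem_type
  }
  if (!is.null(models)) {
    unknown <- setdiff(models, names(reg))
    if (length(unknown)) {
      stop("unknown model(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    reg <- reg[models]
  }
  reg
}

merge_params <- function(default, params) utils::modifyList(default, params %||% list())

as_X <- function(X) {
  m <- as.matrix(X)
  storage.mode(m) <- "double"
  m
}

# ---- random forest ---------------------------------------------------------

fit_rf <- function(X, y, params, seed) {
  X <- as_X(X)
  p <- merge_params(list(n_trees = 100, max_depth = 0, min_leaf = 1, mtry = NULL), params)
  cls <- is.factor(y)
  mtry <- p$mtry %||% if (cls) max(1L, floor(sqrt(ncol(X)))) else max(1L, floor(ncol(X) / 3))
  rng <- local_rng(seed)
  lv <- if (cls) levels(y) else NULL
  ycls <- if (cls) as.integer(y) - 1L else integer(nrow(X))
  ynum <- if (cls) numeric(nrow(X)) else as.numeric(y)
  K <- if (cls) length(lv) else 0L
  trees <- lapply(seq_len(p$n_trees), function(b) {
    idx <- rng$sample_int(nrow(X), nrow(X), replace = TRUE)
    cpp_build_tree(
      X[idx, , drop = FALSE], ynum[idx], ycls[idx], K,
      rep(1, length(idx)), as.integer(p$max_depth), as.integer(p$min_leaf),
      as.integer(mtry), rng$draw_seed()
    )
  })
  structure(
    list(trees = trees, levels = lv, params = p, n_features = ncol(X),
         feature_names = colnames(X)),
    class = c("oml_rf", "oml_model")
  )
}

#' @export
predict.oml_rf <- function(object, newdata, ...) {
  X <- as_X(newdata)
  agg <- Reduce(`+`, lapply(object$trees, function(tr) cpp_predict_tree(tr, X))) /
    length(object$trees)
  if (is.null(object$levels)) {
    return(list(pred = agg[, 1], prob = NULL, raw = agg))
  }
  colnames(agg) <- object$levels
  lab <- factor(object$levels[max.col(agg, ties.method = "first")],
    levels = object$levels
  )
  list(pred = lab, prob = agg, raw = agg)
}

# ---- gradient boosting -----------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# replace leaf values of a regression tree by per-leaf Newton steps
newton_leaves <- function(tree, leaf_idx, g, h, shrink) {
  val <- tree$value
  for (leaf in unique(leaf_idx)) {
    members <- leaf_idx == leaf
    denom <- sum(h[members])
    val[leaf + 1L, 1] <- if (denom > 1e-12) sum(g[members]) / denom else 0
  }
  tree$value <- val * shrink
  tree
}

fit_gbt_core <- function(X, y, p, seed) {
  cls <- is.factor(y)
  rng <- local_rng(seed)
  n <- nrow(X)
  zero <- integer(n)
  if (!cls) {
    f0 <- mean(y)
    Fv <- rep(f0, n)
    trees <- vector("list", p$n_rounds)
    for (m in seq_len(p$n_rounds)) {
      r <- y - Fv
      tr <- cpp_build_tree(
        X, r, zero, 0L, rep(1, n), as.integer(p$max_depth),
        as.integer(p$min_leaf), ncol(X), rng$draw_seed()
      )
      tr$value <- tr$value * p$learning_rate # LS: leaf mean is the exact step
      trees[[m]] <- tr
      Fv <- Fv + cpp_predict_tree(tr, X)[, 1]
    }
    return(list(trees = list(trees), f0 = f0, levels = NULL))
  }
  lv <- levels(y)
  K <- length(lv)
  Y <- outer(as.integer(y), seq_len(K), function(a, b) as.numeric(a == b))
  if (K == 2) {
    # single logit for the second (positive) class
    pbar <- mean(Y[, 2])
    f0 <- log(pbar / (1 - pbar))
    Fv <- rep(f0, n)
    trees <- vector("list", p$n_rounds)
    for (m in seq_len(p$n_rounds)) {
      prob <- sigmoid(Fv)
      g <- Y[, 2] - prob
      h <- pmax(prob * (1 - prob), 1e-12)
      tr <- cpp_build_tree(
        X, g, zero, 0L, rep(1, n), as.integer(p$max_depth),
        as.integer(p$min_leaf), ncol(X), rng$draw_seed()
      )
      tr <- newton_leaves(tr, cpp_leaf_index(tr, X), g, h, p$learning_rate)
      trees[[m]] <- tr
      Fv <- Fv + cpp_predict_tree(tr, X)[, 1]
    }
    return(list(trees = list(trees), f0 = f0, levels = lv))
  }
  # multiclass softmax: one tree per class per round
  Fm <- matrix(0, n, K)
  f0 <- rep(0, K)
  trees <- rep(list(vector("list", p$n_rounds)), K)
  for (m in seq_len(p$n_rounds)) {
    eF <- exp(Fm - apply(Fm, 1, max))
    prob <- eF / rowSums(eF)
    for (k in seq_len(K)) {
      g <- Y[, k] - prob[, k]
      h <- pmax(prob[, k] * (1 - prob[, k]), 1e-12)
      tr <- cpp_build_tree(
        X, g, zero, 0L, rep(1, n), as.integer(p$max_depth),
        as.integer(p$min_leaf), ncol(X), rng$draw_seed()
      )
      tr <- newton_leaves(
        tr, cpp_leaf_index(tr, X), g, h,
        p$learning_rate * (K - 1) / K
      )
      trees[[k]][[m]] <- tr
      Fm[, k] <- Fm[, k] + cpp_predict_tree(tr, X)[, 1]
    }
  }
  list(trees = trees, f0 = f0, levels = lv)
}

fit_gbt <- function(X, y, params, seed) {
  X <- as_X(X)
  p <- merge_params(
    list(n_rounds = 100, learning_rate = 0.1, max_depth = 3, min_leaf = 5),
    params
  )
  core <- fit_gbt_core(X, y, p, seed)
  structure(
    c(core, list(params = p, n_features = ncol(X), feature_names = colnames(X))),
    class = c("oml_gbt", "oml_model")
  )
}

gbt_margin <- function(object, X) {
  if (is.null(object$levels)) {
    f <- rep(object$f0, nrow(X))
    for (tr in object$trees[[1]]) f <- f + cpp_predict_tree(tr, X)[, 1]
    return(matrix(f, ncol = 1))
  }
  K <- length(object$levels)
  if (K == 2) {
    f <- rep(object$f0, nrow(X))
    for (tr in object$trees[[1]]) f <- f + cpp_predict_tree(tr, X)[, 1]
    return(cbind(-f, f) / 1) # symmetric margins for the two classes
  }
  Fm <- matrix(rep(object$f0, each = nrow(X)), nrow(X), K)
  for (k in seq_len(K)) {
    for (tr in object$trees[[k]]) Fm[, k] <- Fm[, k] + cpp_predict_tree(tr, X)[, 1]
  }
  Fm
}

#' @export
predict.oml_gbt <- function(object, newdata, ...) {
  X <- as_X(newdata)
  Fm <- gbt_margin(object, X)
  if (is.null(object$levels)) {
    return(list(pred = Fm[, 1], prob = NULL, raw = Fm))
  }
  K <- length(object$levels)
  prob <- if (K == 2) {
    pr <- sigmoid(Fm[, 2])
    cbind(1 - pr, pr)
  } else {
    eF <- exp(Fm - apply(Fm, 1, max))
    eF / rowSums(eF)
  }
  colnames(prob) <- object$levels
  colnames(Fm) <- object$levels
  lab <- factor(object$levels[max.col(prob, ties.method = "first")],
    levels = object$levels
  )
  list(pred = lab, prob = prob, raw = Fm)
}

# ---- AdaBoost --------------------------------------------------------------

fit_adaboost <- function(X, y, params, seed) {
  X <- as_X(X)
  if (is.factor(y)) fit_adaboost_samme(X, y, params, seed) else fit_adaboost_r2(X, y, params, seed)
}

fit_adaboost_samme <- function(X, y, params, seed) {
  p <- merge_params(list(n_estimators = 50, max_depth = 3, min_leaf = 1), params)
  rng <- local_rng(seed)
  n <- nrow(X)
  lv <- levels(y)
  K <- length(lv)
  ycls <- as.integer(y) - 1L
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric()
  for (m in seq_len(p$n_estimators)) {
    tr <- cpp_build_tree(
      X, numeric(n), ycls, K, w, as.integer(p$max_depth),
      as.integer(p$min_leaf), ncol(X), rng$draw_seed()
    )
    pred <- max.col(cpp_predict_tree(tr, X), ties.method = "first") - 1L
    miss <- pred != ycls
    err <- sum(w[miss])
    if (err <= 0) { # perfect weak learner: keep it alone and stop
      trees <- c(trees, list(tr))
      alphas <- c(alphas, 1)
      break
    }
    if (err >= 1 - 1 / K) {
      if (!length(trees)) {
        trees <- list(tr)
        alphas <- 1
      }
      break
    }
    alpha <- log((1 - err) / err) + log(K - 1)
    trees <- c(trees, list(tr))
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  structure(
    list(
      trees = trees, alphas = alphas, levels = lv, params = p,
      n_features = ncol(X), feature_names = colnames(X)
    ),
    class = c("oml_adaboost", "oml_model")
  )
}

# alpha-weighted vote matrix (samples x classes)
adaboost_votes <- function(object, X) {
  K <- length(object$levels)
  V <- matrix(0, nrow(X), K)
  for (m in seq_along(object$trees)) {
    pred <- max.col(cpp_predict_tree(object$trees[[m]], X), ties.method = "first")
    V <- V + object$alphas[m] * (matrix(seq_len(K),
      nrow(X), K,
      byrow = TRUE
    ) == pred)
  }
  colnames(V) <- object$levels
  V
}

#' @export
predict.oml_adaboost <- function(object, newdata, ...) {
  X <- as_X(newdata)
  V <- adaboost_votes(object, X)
  prob <- V / pmax(rowSums(V), 1e-12)
  lab <- factor(object$levels[max.col(V, ties.method = "first")],
    levels = object$levels
  )
  list(pred = lab, prob = prob, raw = V)
}

fit_adaboost_r2 <- function(X, y, params, seed) {
  p <- merge_params(list(n_estimators = 50, max_depth = 3, min_leaf = 1), params)
  rng <- local_rng(seed)
  n <- nrow(X)
  w <- rep(1 / n, n)
  zero <- integer(n)
  trees <- list()
  betas <- numeric()
  for (m in seq_len(p$n_estimators)) {
    tr <- cpp_build_tree(
      X, as.numeric(y), zero, 0L, w, as.integer(p$max_depth),
      as.integer(p$min_leaf), ncol(X), rng$draw_seed()
    )
    pred <- cpp_predict_tree(tr, X)[, 1]
    abs_err <- abs(pred - y)
    emax <- max(abs_err)
    if (emax == 0) {
      trees <- c(trees, list(tr))
      betas <- c(betas, 1e-10)
      break
    }
    lbar <- sum(w * abs_err / emax)
    if (lbar >= 0.5) {
      if (!length(trees)) {
        trees <- list(tr)
        betas <- 0.5
      }
      break
    }
    beta <- lbar / (1 - lbar)
    trees <- c(trees, list(tr))
    betas <- c(betas, beta)
    w <- w * beta^(1 - abs_err / emax)
    w <- w / sum(w)
  }
  structure(
    list(
      trees = trees, betas = betas, levels = NULL, params = p,
      n_features = ncol(X), feature_names = colnames(X)
    ),
    class = c("oml_adaboost_r2", "oml_model")
  )
}

#' @export
predict.oml_adaboost_r2 <- function(object, newdata, ...) {
  X <- as_X(newdata)
  preds <- vapply(object$trees, function(tr) cpp_predict_tree(tr, X)[, 1],
    numeric(nrow(X))
  )
  if (nrow(X) == 1) preds <- matrix(preds, nrow = 1)
  wts <- log(1 / object$betas)
  out <- apply(preds, 1, function(row) { # weighted median
    o <- order(row)
    cw <- cumsum(wts[o])
    row[o][which(cw >= sum(wts) / 2)[1]]
  })
  list(pred = out, prob = NULL, raw = matrix(out, ncol = 1))
}

# ---- k-nearest neighbours --------------------------------------------------

fit_knn <- function(X, y, params, seed) {
  X <- as_X(X)
  p <- merge_params(list(k = 5), params)
  structure(
    list(
      X = X, y = y, levels = if (is.factor(y)) levels(y) else NULL,
      params = p, n_features = ncol(X), feature_names = colnames(X)
    ),
    class = c("oml_knn", "oml_model")
  )
}

#' @export
predict.oml_knn <- function(object, newdata, ...) {
  Xq <- as_X(newdata)
  Xt <- object$X
  k <- min(object$params$k, nrow(Xt))
  d2 <- outer(rowSums(Xq^2), rowSums(Xt^2), "+") - 2 * Xq %*% t(Xt)
  if (is.null(object$levels)) {
    pred <- apply(d2, 1, function(row) mean(object$y[order(row)[seq_len(k)]]))
    return(list(pred = pred, prob = NULL, raw = matrix(pred, ncol = 1)))
  }
  lv <- object$levels
  prob <- t(apply(d2, 1, function(row) {
    nb <- object$y[order(row)[seq_len(k)]]
    tabulate(as.integer(nb), nbins = length(lv)) / k
  }))
  colnames(prob) <- lv
  lab <- factor(lv[max.col(prob, ties.method = "first")], levels = lv)
  list(pred = lab, prob = prob, raw = prob)
}

# ---- histogram-binned boosting (LightGBM-style) ----------------------------

fit_bin_map <- function(X, max_bin) {
  lapply(seq_len(ncol(X)), function(j) {
    qs <- unique(stats::quantile(X[, j],
      probs = seq(0, 1, length.out = max_bin + 1),
      type = 7
    ))
    qs
  })
}

apply_bin_map <- function(X, bins) {
  out <- X
  for (j in seq_len(ncol(X))) {
    qs <- bins[[j]]
    if (length(qs) <= 2) next
    cuts <- qs[-c(1, length(qs))]
    mids <- (qs[-length(qs)] + qs[-1]) / 2
    idx <- findInterval(X[, j], cuts, left.open = FALSE) + 1L
    out[, j] <- mids[idx]
  }
  out
}

fit_binned_gbt <- function(X, y, params, seed) {
  X <- as_X(X)
  p <- merge_params(
    list(
      n_rounds = 100, learning_rate = 0.1, max_depth = 5, min_leaf = 5,
      max_bin = 63
    ),
    params
  )
  bins <- fit_bin_map(X, p$max_bin)
  core <- fit_gbt_core(apply_bin_map(X, bins), y, p, seed)
  structure(
    c(core, list(
      params = p, bins = bins, n_features = ncol(X),
      feature_names = colnames(X)
    )),
    class = c("oml_binned_gbt", "oml_gbt", "oml_model")
  )
}

#' @export
predict.oml_binned_gbt <- function(object, newdata, ...) {
  Xb <- apply_bin_map(as_X(newdata), object$bins)
  class(object) <- c("oml_gbt", "oml_model")
  predict(object, Xb)
}
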