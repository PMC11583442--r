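#' Model explanations
#'
#' Two complementary views of a fitted model. *Permutation importance*: the
#' drop in an evaluation score when one feature column is shuffled, averaged
#' over seeded repeats -- a global, model-agnostic ranking. *Shapley
#' attributions*: per-sample, per-feature additive contributions whose sum
#' plus a base value equals the model's output for that sample (per class
#' for classification). Tree ensembles get exact path-dependent tree
#' attributions (computed in compiled code); models without an exact tree
#' decomposition (k-nearest neighbours; AdaBoost.R2, whose weighted-median
#' aggregation is not leaf-additive) use a seeded permutation-sampling
#' approximation.
#'
#' Attribution scales per model: random forests are explained on the class
#' probability scale (a forest's raw output), gradient-boosted models on the
#' per-class margin (log-odds) scale, AdaBoost classifiers on the
#' alpha-weighted vote scale; additivity is exact on each model's own raw
#' output scale.
#'
#' @name explain
NULL

#' Permutation importance
#'
#' `importance_j` is the mean over `repeats` seeded shuffles of the baseline
#' score minus the score with column `j` permuted (sign flipped for
#' error-type metrics, so larger is always more important). The baseline is
#' computed once.
#'
#' @param model A fitted `oml_model`.
#' @param X Evaluation matrix (train or test partition, per configuration).
#' @param y Evaluation target.
#' @param metric Metric name.
#' @param repeats Number of shuffles per feature (default 5).
#' @param seed Integer seed; identical seeds give identical importances.
#' @return A tibble: `feature`, `importance` (mean), `sd`.
#' @export
permutation_importance <- function(model, X, y, metric, repeats = 5, seed = 42) {
  X <- as_X(X)
  rng <- local_rng(seed)
  score_of <- function(M) {
    out <- predict(model, M)
    compute_metric(metric, y, out$pred, out$prob)
  }
  baseline <- score_of(X)
  sign <- if (metric_orientation(metric) == "score") 1 else -1
  drops <- matrix(0, ncol(X), repeats)
  for (r in seq_len(repeats)) {
    perm <- rng$sample_int(nrow(X))
    for (j in seq_len(ncol(X))) {
      Xp <- X
      Xp[, j] <- X[perm, j]
      drops[j, r] <- sign * (baseline - score_of(Xp))
    }
  }
  tibble::tibble(
    feature = colnames(X),
    importance = rowMeans(drops),
    sd = apply(drops, 1, stats::sd)
  )
}

# ---- Shapley attributions --------------------------------------------------

# exact attributions of an additive tree ensemble for one output dimension
ensemble_shap <- function(trees, X, out_dim, scale = 1) {
  phi <- matrix(0, nrow(X), ncol(X))
  base <- 0
  for (tr in trees) {
    ph <- cpp_tree_shap(tr, X, as.integer(out_dim))
    base <- base + attr(ph, "base") * scale
    phi <- phi + ph * scale
  }
  colnames(phi) <- colnames(X)
  list(phi = phi, base = base)
}

shap_tree_model <- function(model, X) {
  UseMethod("shap_tree_model")
}

#' @export
shap_tree_model.oml_rf <- function(model, X) {
  B <- length(model$trees)
  if (is.null(model$levels)) {
    s <- ensemble_shap(model$trees, X, 0, scale = 1 / B)
    return(list(attributions = list(value = s$phi), base_values = c(value = s$base)))
  }
  out <- lapply(seq_along(model$levels) - 1L, function(k) {
    ensemble_shap(model$trees, X, k, scale = 1 / B)
  })
  list(
    attributions = stats::setNames(lapply(out, `[[`, "phi"), model$levels),
    base_values = stats::setNames(vapply(out, `[[`, 0, "base"), model$levels)
  )
}

#' @export
shap_tree_model.oml_gbt <- function(model, X) {
  if (is.null(model$levels)) {
    s <- ensemble_shap(model$trees[[1]], X, 0)
    return(list(
      attributions = list(value = s$phi),
      base_values = c(value = s$base + model$f0)
    ))
  }
  K <- length(model$levels)
  if (K == 2) {
    s <- ensemble_shap(model$trees[[1]], X, 0)
    return(list(
      attributions = stats::setNames(list(-s$phi, s$phi), model$levels),
      base_values = stats::setNames(
        c(-(s$base + model$f0), s$base + model$f0),
        model$levels
      )
    ))
  }
  out <- lapply(seq_len(K), function(k) ensemble_shap(model$trees[[k]], X, 0))
  list(
    attributions = stats::setNames(lapply(out, `[[`, "phi"), model$levels),
    base_values = stats::setNames(
      vapply(out, `[[`, 0, "base") + model$f0, model$levels
    )
  )
}

#' @export
shap_tree_model.oml_binned_gbt <- function(model, X) {
  Xb <- apply_bin_map(X, model$bins)
  class(model) <- c("oml_gbt", "oml_model")
  shap_tree_model(model, Xb)
}

# SAMME: leaf value for class c becomes alpha * 1{leaf majority class == c}
#' @export
shap_tree_model.oml_adaboost <- function(model, X) {
  K <- length(model$levels)
  vote_trees <- lapply(seq_along(model$trees), function(m) {
    tr <- model$trees[[m]]
    winner <- max.col(tr$value, ties.method = "first")
    tr$value <- model$alphas[m] *
      (matrix(seq_len(K), nrow(tr$value), K, byrow = TRUE) == winner)
    tr
  })
  out <- lapply(seq_len(K) - 1L, function(k) ensemble_shap(vote_trees, X, k))
  list(
    attributions = stats::setNames(lapply(out, `[[`, "phi"), model$levels),
    base_values = stats::setNames(vapply(out, `[[`, 0, "base"), model$levels)
  )
}

# Monte-Carlo permutation sampling (model-agnostic fallback)
sampling_shap <- function(model, X, background, n_perm = 64, seed = 42) {
  rng <- local_rng(seed)
  p <- ncol(X)
  raw_of <- function(M) predict(model, M)$raw
  base_out <- colMeans(raw_of(background))
  n_out <- length(base_out)
  phis <- lapply(seq_len(n_out), function(k) matrix(0, nrow(X), p))
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    acc <- matrix(0, n_out, p)
    for (s in seq_len(n_perm)) {
      ord <- rng$sample_int(p)
      b <- background[rng$sample_int(nrow(background), 1), ]
      # rows 1..p+1: background row with successively more features set to x
      Z <- matrix(b, p + 1, p, byrow = TRUE)
      z <- b
      for (step in seq_len(p)) {
        z[ord[step]] <- x[ord[step]]
        Z[step + 1, ] <- z
      }
      colnames(Z) <- colnames(X)
      out <- raw_of(Z)
      for (k in seq_len(n_out)) {
        acc[k, ord] <- acc[k, ord] + diff(out[, k])
      }
    }
    for (k in seq_len(n_out)) phis[[k]][i, ] <- acc[k, ] / n_perm
  }
  for (k in seq_len(n_out)) colnames(phis[[k]]) <- colnames(X)
  nm <- colnames(raw_of(X[1, , drop = FALSE])) %||% "value"
  if (length(nm) != n_out) nm <- paste0("out", seq_len(n_out))
  list(
    attributions = stats::setNames(phis, nm),
    base_values = stats::setNames(base_out, nm)
  )
}

#' Shapley-value explanations of a fitted model
#'
#' Exact tree-path attribution for tree ensembles, seeded sampling
#' approximation otherwise. Returns per-class (classification) or single
#' (regression) samples-by-features attribution matrices, base values, and
#' the global ranking by mean absolute attribution.
#'
#' @param model A fitted `oml_model` (or an `oml_model_result`).
#' @param X_explain Matrix of samples to explain (training set, test set, or
#'   both, per configuration).
#' @param top_n Length of the global ranking (default 15).
#' @param background Background data for the sampling approximation
#'   (defaults to `X_explain`).
#' @param seed Seed for the sampling approximation.
#' @return An `oml_explanations` bundle: `attributions` (list of matrices),
#'   `base_values`, `ranking` (tibble), `X_explain`, `method`.
#' @export
shapley_explanations <- function(model, X_explain, top_n = 15,
                                 background = NULL, seed = 42) {
  if (inherits(model, "oml_model_result")) model <- model$model
  X <- as_X(X_explain)
  exact <- inherits(model, c("oml_rf", "oml_gbt", "oml_adaboost")) &&
    !inherits(model, "oml_adaboost_r2")
  res <- if (exact) {
    shap_tree_model(model, X)
  } else {
    sampling_shap(model, X, background %||% X, seed = seed)
  }
  mean_abs <- vapply(
    res$attributions,
    function(phi) colMeans(abs(phi)), numeric(ncol(X))
  )
  if (is.null(dim(mean_abs))) mean_abs <- matrix(mean_abs, ncol = length(res$attributions))
  overall <- rowSums(mean_abs)
  ord <- order(-overall)
  ranking <- tibble::tibble(
    feature = colnames(X)[ord],
    mean_abs_attribution = overall[ord]
  )[seq_len(min(top_n, ncol(X))), ]
  structure(
    list(
      attributions = res$attributions,
      base_values = res$base_values,
      ranking = ranking,
      X_explain = X,
      method = if (exact) "exact_tree_path" else "permutation_sampling",
      top_n = top_n
    ),
    class = "oml_explanations"
  )
}

#' @export
print.oml_explanations <- function(x, ...) {
  cat(
    "<oml_explanations>", x$method, "|", nrow(x$X_explain), "samples x",
    ncol(x$X_explain), "features,", length(x$attributions), "output(s)\n"
  )
  cat("top features:", paste(utils::head(x$ranking$feature, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy Shapley explanations
#'
#' Long-format attributions: one row per sample, feature and output class,
#' with the feature value alongside (dot-plot data).
#'
#' @param x An `oml_explanations` bundle.
#' @param ... Unused.
#' @return A tibble: `class`, `sample`, `feature`, `attribution`, `value`.
#' @method tidy oml_explanations
#' @export
tidy.oml_explanations <- function(x, ...) {
  purrr::imap_dfr(x$attributions, function(phi, cls) {
    tibble::tibble(
      class = cls,
      sample = rep(rownames(x$X_explain) %||% as.character(seq_len(nrow(phi))),
        times = ncol(phi)
      ),
      feature = rep(colnames(phi), each = nrow(phi)),
      attribution = as.vector(phi),
      value = as.vector(x$X_explain)
    )
  })
}

#' Export explanation tables as CSV files
#'
#' Writes `permutimp_TopFeatures_info_[NameOfModel].csv` (permutation
#' importances with mean and sd) and one
#' `shapley_values_all_[NameOfModelAndClassIfApplicable].csv` per output
#' class (a samples-by-features table of attributions; a single file for
#' regression).
#'
#' @param explanations An `oml_explanations` bundle.
#' @param permimp Permutation-importance tibble from
#'   [permutation_importance()] (or `NULL` to skip).
#' @param model_name Registry name embedded in the file names.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_explanations <- function(explanations, permimp, model_name, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (!is.null(permimp)) {
    ord <- order(-permimp$importance)
    top <- permimp[ord, ][seq_len(min(explanations$top_n, nrow(permimp))), ]
    path <- file.path(out_dir, paste0("permutimp_TopFeatures_info_", model_name, ".csv"))
    readr::write_csv(top, path)
    paths <- c(paths, path)
  }
  single <- length(explanations$attributions) == 1
  for (cls in names(explanations$attributions)) {
    phi <- explanations$attributions[[cls]]
    tag <- if (single) model_name else paste0(model_name, "_", cls)
    path <- file.path(out_dir, paste0("shapley_values_all_", tag, ".csv"))
    df <- tibble::as_tibble(as.data.frame(phi, check.names = FALSE))
    df <- dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(explanations$X_explain) %||%
        as.character(seq_len(nrow(phi)))),
      df
    )
    readr::write_csv(df, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
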