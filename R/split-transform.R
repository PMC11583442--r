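#' Train/test splitting and quantile standardisation
#'
#' The split is deterministic given the seed; classification splits are
#' stratified by class so that minority classes are represented in both
#' partitions (this protects class-balance-sensitive model selection).
#' Standardisation maps each feature through its *training-set* empirical CDF
#' to \[0, 1\] -- robust to the skewed marginals typical of omics data. The
#' map is fitted on the training partition only and applied unchanged to the
#' test partition: test rows never influence any fitted parameter.
#'
#' @name split_transform
NULL

#' Split samples into train and test partitions
#'
#' @param table Feature table.
#' @param target Target tibble aligned to `table`.
#' @param test_size Proportion of samples held out (default 0.2).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param stratify Stratify by class; default `TRUE` for factor targets.
#' @return An object of class `oml_split`: list with `train`/`test`
#'   (each `table` + `target`), `seed`, `test_size`.
#' @export
split_train_test <- function(table, target, test_size = 0.2, seed = 42,
                             stratify = is.factor(target$target)) {
  table <- as_feature_table(table)
  n <- nrow(table)
  if (n < 5) stop("need at least 5 samples to split", call. = FALSE)
  if (test_size <= 0 || test_size >= 1) stop("test_size must be in (0,1)", call. = FALSE)
  if (!identical(table$sample_id, target$sample_id)) {
    stop("table and target are not aligned; call align_samples() first", call. = FALSE)
  }
  rng <- local_rng(seed)
  if (stratify) {
    y <- factor(target$target)
    if (any(table(y) < 2)) {
      stop("every class needs at least 2 members to stratify; offending class: ",
        names(which(table(y) < 2))[1],
        call. = FALSE
      )
    }
    test_idx <- integer()
    for (lv in levels(y)) {
      idx <- which(y == lv)
      n_test <- round(test_size * length(idx))
      n_test <- max(min(n_test, length(idx) - 1L), 0L)
      test_idx <- c(test_idx, rng$sample(idx, n_test))
    }
  } else {
    n_test <- max(1L, round(test_size * n))
    test_idx <- rng$sample(seq_len(n), n_test)
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  structure(
    list(
      train = list(
        table = table[train_idx, , drop = FALSE],
        target = target[train_idx, , drop = FALSE]
      ),
      test = list(
        table = table[test_idx, , drop = FALSE],
        target = target[test_idx, , drop = FALSE]
      ),
      seed = seed, test_size = test_size
    ),
    class = "oml_split"
  )
}

#' @export
print.oml_split <- function(x, ...) {
  cat(
    "<oml_split>", nrow(x$train$table), "train /", nrow(x$test$table),
    "test samples,", length(ft_features(x$train$table)), "features\n"
  )
  invisible(x)
}

#' Fit a per-feature quantile map on training data
#'
#' Stores, per feature, the empirical quantiles at
#' `q = min(n_quantiles, n_train)` evenly spaced probability levels. Constant
#' features get a degenerate grid and transform to 0.
#'
#' @param train Feature table of training samples (at least 2 rows).
#' @param n_quantiles Upper bound on grid size (default 1000).
#' @return An object of class `oml_quantile_map`.
#' @export
fit_quantile_map <- function(train, n_quantiles = 1000) {
  train <- as_feature_table(train)
  m <- ft_matrix(train)
  if (nrow(m) < 2) stop("need at least 2 training rows", call. = FALSE)
  q <- min(n_quantiles, nrow(m))
  probs <- seq(0, 1, length.out = q)
  grids <- lapply(seq_len(ncol(m)), function(j) {
    unname(stats::quantile(m[, j], probs = probs, type = 7))
  })
  names(grids) <- colnames(m)
  structure(
    list(grids = grids, probs = probs, n_train = nrow(m)),
    class = "oml_quantile_map"
  )
}

# one feature: empirical-CDF interpolation with midpoint ties and clipping
quantile_transform_col <- function(v, grid, probs) {
  qu <- unique(grid)
  if (length(qu) == 1L) {
    return(rep(0, length(v)))
  }
  # probability range occupied by each unique grid value
  p_lo <- probs[match(qu, grid)]
  p_hi <- probs[length(grid) + 1L - match(qu, rev(grid))]
  lower <- stats::approx(qu, p_lo, xout = v, rule = 2)$y
  upper <- stats::approx(qu, p_hi, xout = v, rule = 2)$y
  out <- ifelse(v %in% qu, (lower + upper) / 2,
    # between distinct grid values both interpolants agree on the segment
    stats::approx(qu, (p_lo + p_hi) / 2, xout = v, rule = 2)$y
  )
  out[v <= qu[1]] <- 0
  out[v >= qu[length(qu)]] <- 1
  pmin(pmax(out, 0), 1)
}

#' Apply a fitted quantile map
#'
#' Values are mapped by linear interpolation of the training empirical CDF to
#' \[0, 1\]; values outside the training range clip to 0 or 1; tied training
#' values share the midpoint of their probability range. The map is monotone
#' non-decreasing per feature.
#'
#' @param map An `oml_quantile_map` from [fit_quantile_map()].
#' @param table Feature table whose features all appear in the map.
#' @return Transformed feature table with values in \[0, 1\].
#' @export
apply_quantile_map <- function(map, table) {
  table <- as_feature_table(table)
  feats <- ft_features(table)
  unseen <- setdiff(feats, names(map$grids))
  if (length(unseen)) {
    stop("feature(s) absent from the fitted map: ",
      paste(utils::head(unseen, 5), collapse = ", "),
      call. = FALSE
    )
  }
  m <- ft_matrix(table)
  out <- m
  for (j in seq_len(ncol(m))) {
    out[, j] <- quantile_transform_col(m[, j], map$grids[[feats[j]]], map$probs)
  }
  ft_from_matrix(out)
}

#' @export
print.oml_quantile_map <- function(x, ...) {
  cat(
    "<oml_quantile_map>", length(x$grids), "features,",
    length(x$probs), "quantile levels (n_train =", x$n_train, ")\n"
  )
  invisible(x)
}
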