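#' Class rebalancing of the training partition
#'
#' Plain random resampling, applied to the training partition only and after
#' feature selection (the test partition is never rebalanced). Oversampling
#' resamples minority classes with replacement up to the majority count, so
#' every original row is retained and duplicated rows are exact copies;
#' undersampling subsamples majority classes without replacement down to the
#' minority count.
#'
#' @param X Numeric training matrix (samples x features, rownames = IDs).
#' @param y Factor of training labels, aligned to `X`.
#' @param strategy `"none"`, `"oversample"`, or `"undersample"`.
#' @param seed Integer seed; resampling is deterministic given the seed.
#' @return List with rebalanced `X` and `y`.
#' @export
rebalance <- function(X, y, strategy = c("none", "oversample", "undersample"),
                      seed = 42) {
  strategy <- match.arg(strategy)
  if (!is.factor(y)) stop("rebalance applies to classification targets only", call. = FALSE)
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes", call. = FALSE)
  if (strategy == "none") {
    return(list(X = X, y = y))
  }
  counts <- table(y)
  rng <- local_rng(seed)
  idx <- integer()
  for (lv in levels(y)) {
    members <- which(y == lv)
    if (strategy == "oversample") {
      n_extra <- max(counts) - length(members)
      extra <- if (n_extra > 0) rng$sample(members, n_extra, replace = TRUE) else integer()
      idx <- c(idx, members, extra) # originals always kept
    } else {
      idx <- c(idx, sort(rng$sample(members, min(counts))))
    }
  }
  list(X = X[idx, , drop = FALSE], y = y[idx])
}
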