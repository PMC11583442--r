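# Independent oracles and tiny fixture builders shared across tests.
# These deliberately re-derive quantities from first principles (explicit
# loops, enumeration) rather than calling the package's own code paths.

# small random feature table
random_table <- function(n = 10, p = 8, rng = function(k) rpois(k, 5), prefix = "f") {
  m <- matrix(rng(n * p), n, p)
  colnames(m) <- paste0(prefix, seq_len(p))
  rownames(m) <- paste0("s", seq_len(n))
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(as.data.frame(m))
  )
}

table_matrix <- function(tab) {
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  m
}

# --- TMM: direct transcription of the trimmed-mean-of-M-values definition ---
# reference = sample whose upper quartile (of depth-normalised counts) is
# closest to the mean; M = log2 depth-normalised ratio; A = mean log2
# abundance; double trim 30% (M) / 5% (A); precision-weighted mean of the
# retained M; factors rescaled to geometric mean 1.
tmm_factors_oracle <- function(m) {
  lib <- rowSums(m)
  f75 <- vapply(seq_len(nrow(m)), function(i) {
    unname(stats::quantile(m[i, ], 0.75)) / lib[i]
  }, 0)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(nrow(m)), function(i) {
    obs <- m[i, ]
    refc <- m[ref, ]
    nO <- lib[i]
    nR <- lib[ref]
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE) # drops pairs with a zero count
    logR <- logR[fin]
    absE <- absE[fin]
    v <- v[fin]
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1
    hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }, 0)
  f / exp(mean(log(f)))
}

# --- path-dependent expectation of a tree given a feature subset S ----------
tree_expvalue <- function(tree, x, S) {
  rec <- function(node) {
    f <- tree$feature[node + 1]
    if (f < 0) {
      return(tree$value[node + 1, 1])
    }
    l <- tree$left[node + 1]
    r <- tree$right[node + 1]
    if ((f + 1) %in% S) {
      if (x[f + 1] <= tree$threshold[node + 1]) rec(l) else rec(r)
    } else {
      (tree$cover[l + 1] * rec(l) + tree$cover[r + 1] * rec(r)) / tree$cover[node + 1]
    }
  }
  rec(0)
}

# brute-force Shapley values of one tree by subset enumeration
tree_shap_brute <- function(tree, x, p) {
  vapply(seq_len(p), function(j) {
    others <- setdiff(seq_len(p), j)
    total <- 0
    for (sz in 0:length(others)) {
      combs <- if (sz == 0) list(integer()) else asplit(utils::combn(others, sz), 2)
      for (S in combs) {
        w <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
        total <- total + w * (tree_expvalue(tree, x, c(S, j)) - tree_expvalue(tree, x, S))
      }
    }
    total
  }, 0)
}

# --- stable-window rule by exhaustive enumeration ---------------------------
pick_window_brute <- function(ks, scores, orientation) {
  n_win <- length(ks) - 2
  best_i <- NA
  best_crit <- -Inf
  best_m <- -Inf
  for (i in seq_len(n_win)) {
    w <- scores[i:(i + 2)]
    m <- mean(w)
    s <- stats::sd(w)
    crit <- if (orientation == "score") m - s else -(m + s)
    mm <- if (orientation == "score") m else -m
    better <- crit > best_crit + 1e-12 ||
      (abs(crit - best_crit) <= 1e-12 &&
        (mm > best_m + 1e-12 || (abs(mm - best_m) <= 1e-12 && i > best_i)))
    if (is.na(best_i) || better) {
      best_i <- i
      best_crit <- crit
      best_m <- mm
    }
  }
  ks[best_i + 2]
}

# --- one-way ANOVA F by explicit group loops --------------------------------
f_classif_brute <- function(x, y) {
  y <- factor(y)
  groups <- levels(y)
  N <- length(x)
  G <- length(groups)
  grand <- mean(x)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    xs <- x[y == g]
    ssb <- ssb + length(xs) * (mean(xs) - grand)^2
    ssw <- ssw + sum((xs - mean(xs))^2)
  }
  (ssb / (G - 1)) / (ssw / (N - G))
}

f_regression_brute <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r^2 / (1 - r^2) * (length(x) - 2)
}

# quiet wrapper: pre-processing functions message() their reports
quietly <- function(expr) suppressMessages(expr)
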