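test_that("variance filter keeps features strictly above the threshold", {
  tab <- tibble::tibble(
    sample_id = paste0("s", 1:10),
    const = rep(5, 10),
    spread = c(rep(0, 5), rep(sqrt(2), 5)), # population variance 0.5
    wide = rnorm(10, sd = 10)
  )
  out <- variance_filter(tab, 0)
  expect_identical(names(out$table)[-1], c("spread", "wide"))
  expect_identical(out$removed, "const")
  out2 <- variance_filter(tab, 0.4) # 0.5 > 0.4 kept
  expect_true("spread" %in% names(out2$table))
  expect_error(variance_filter(tab, 1e9), "no features remain")
})

test_that("univariate F scores match brute-force closed forms", {
  set.seed(7)
  # classification: random 2-group toys vs explicit sums of squares
  for (i in 1:25) {
    n <- sample(10:30, 1)
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
    while (length(unique(y)) < 2) y <- factor(sample(c("a", "b"), n, replace = TRUE))
    f <- f_classif_scores(X, y)
    for (j in 1:4) expect_equal(unname(f[j]), f_classif_brute(X[, j], y), tolerance = 1e-10)
  }
  # regression: F = r^2/(1-r^2) * (n-2)
  for (i in 1:25) {
    n <- 20
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
    y <- rnorm(n)
    f <- f_regression_scores(X, y)
    for (j in 1:3) expect_equal(unname(f[j]), f_regression_brute(X[, j], y), tolerance = 1e-10)
  }
})

test_that("degenerate univariate scores follow the documented conventions", {
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  X <- cbind(
    const = rep(1, 6), # constant -> 0 with warning
    perfect = c(0, 0, 0, 1, 1, 1) # zero within-variance -> Inf, ranked first
  )
  expect_warning(f <- f_classif_scores(X, y), "constant")
  expect_identical(unname(f["const"]), 0)
  expect_identical(unname(f["perfect"]), Inf)
  expect_identical(select_k_best(f, 1), "perfect")

  # regression: exact linear target -> Inf; orthogonal feature -> 0
  x <- rnorm(20)
  Xr <- cbind(lin = x, orth = rep(c(-1, 1), 10))
  yr <- 2 * x + 3
  fr <- f_regression_scores(Xr, yr)
  expect_identical(unname(fr["lin"]), Inf)
  expect_lt(unname(fr["orth"]), f_regression_brute(Xr[, "orth"], yr) + 1e-8)
})

test_that("k-best selection breaks ties by input order and nests", {
  scores <- c(a = 3, b = 1, c = 2)
  expect_identical(select_k_best(scores, 2), c("a", "c"))
  expect_identical(select_k_best(scores, 3), c("a", "b", "c")) # identity
  expect_error(select_k_best(scores, 0), "k must be")
  expect_error(select_k_best(scores, 4), "k must be")

  tied <- c(x = 1, y = 1, z = 1)
  expect_identical(select_k_best(tied, 2), c("x", "y")) # first two in input order

  # nestedness under distinct scores
  set.seed(23)
  s <- setNames(sample(seq(0.01, 1, length.out = 30)), paste0("f", 1:30))
  for (k in 1:29) {
    expect_true(all(select_k_best(s, k) %in% select_k_best(s, k + 1)))
  }
})

test_that("candidate ks are log-spaced, unique, and include both endpoints", {
  ks <- candidate_ks(2, 500)
  expect_true(all(diff(ks) > 0))
  expect_identical(ks[1], 2)
  expect_identical(ks[length(ks)], 500)
  expect_lte(length(ks), 12)
  # roughly geometric spacing
  expect_lt(sd(diff(log(ks))), mean(diff(log(ks))))
  expect_error(candidate_ks(10, 10), "auto_min")
})

test_that("the stable-window rule matches exhaustive enumeration", {
  set.seed(29)
  for (i in 1:300) {
    n_k <- sample(3:12, 1)
    ks <- sort(sample(2:500, n_k))
    scores <- round(runif(n_k), sample(c(1, 2, 6), 1)) # coarse rounding forces ties
    for (orientation in c("score", "error")) {
      got <- pick_stable_window(ks, scores, orientation)$k
      expect_identical(got, pick_window_brute(ks, scores, orientation))
    }
  }

  # all scores identical -> every window ties -> largest k wins
  expect_identical(pick_stable_window(c(2, 4, 8, 16, 32), rep(0.8, 5), "score")$k, 32)

  # rising-then-flat curve: chosen k inside the flat region
  ks <- c(2, 4, 8, 16, 32, 64)
  scores <- c(0.5, 0.7, 0.9, 0.9, 0.9, 0.9) # flat from k = 8
  expect_gte(pick_stable_window(ks, scores, "score")$k, 8)

  # a V-shaped spike is never chosen
  scores_v <- c(0.5, 0.5, 0.95, 0.5, 0.5, 0.5)
  expect_false(pick_stable_window(ks, scores_v, "score")$k == 8)
})

test_that("automated k recovers planted features on easy synthetic data", {
  gen <- make_classification_table(
    n = 120, p = 60, n_informative = 6, effect = 3, seed = 31
  )
  X <- table_matrix(gen$table)
  y <- gen$target$target
  res <- auto_select_k(X, y, auto_min = 2, auto_max = 32, seed = 11)
  expect_s3_class(res$curve, "oml_selection_curve")
  expect_identical(attr(res$curve, "chosen_k"), res$k)
  expect_true(res$k %in% res$curve$k)
  sel <- select_k_best(f_classif_scores(X, y), res$k)
  expect_gte(length(intersect(sel, gen$truth$informative)), 5)

  # determinism of the whole search
  res2 <- auto_select_k(X, y, auto_min = 2, auto_max = 32, seed = 11)
  expect_identical(res$curve$score, res2$curve$score)
  expect_identical(res$k, res2$k)
})

test_that("run_feature_selection handles null, fixed-k, and auto modes", {
  gen <- make_classification_table(n = 50, p = 20, n_informative = 4, seed = 5)
  y <- gen$target$target
  # null config: identity
  expect_identical(
    run_feature_selection(gen$table, y, NULL)$features,
    names(gen$table)[-1]
  )
  # fixed k
  out <- run_feature_selection(gen$table, y, list(k = 5))
  expect_length(out$features, 5)
  expect_error(
    run_feature_selection(gen$table, y, list(k = 100)),
    "exceeds"
  )
  # auto produces a curve
  out_auto <- run_feature_selection(
    gen$table, y, list(k = "auto", auto_min = 2, auto_max = 16),
    scoring = "f1", seed = 1
  )
  expect_s3_class(out_auto$curve, "oml_selection_curve")
  expect_length(out_auto$features, out_auto$curve |> attr("chosen_k"))
})
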