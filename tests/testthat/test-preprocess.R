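# Data-type-specific filters. Each test checks the documented boundary
# behaviour plus agreement with a brute-force scan where the spec of the
# rule is arithmetic.

test_that("TMM normalisation: symmetry, depth invariance, oracle agreement", {
  set.seed(11)
  # identical samples -> unit factors, equal outputs
  tab <- random_table(2, 30, rng = function(k) rpois(k, 20))
  tab[2, -1] <- tab[1, -1]
  out <- quietly(tmm_normalize(tab))
  f <- attr(out, "norm_factors")
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  expect_equal(unlist(out[1, -1]), unlist(out[2, -1]), tolerance = 1e-12)

  # doubling a sample's depth leaves the M-values unchanged, so the factors
  # move only through the depth-dependent precision weights (sub-1% here)
  tab <- random_table(4, 40, rng = function(k) rpois(k, 30) + 1)
  f1 <- attr(quietly(tmm_normalize(tab)), "norm_factors")
  tab2 <- tab
  tab2[2, -1] <- tab2[2, -1] * 2
  f2 <- attr(quietly(tmm_normalize(tab2)), "norm_factors")
  expect_equal(unname(f1), unname(f2), tolerance = 0.01)

  # random 4 x 20 matrices match the direct transcription of the definition
  for (i in 1:10) {
    tab <- random_table(4, 20, rng = function(k) rpois(k, 15) + 1)
    m <- table_matrix(tab)
    f <- attr(quietly(tmm_normalize(tab)), "norm_factors")
    expect_equal(unname(f), tmm_factors_oracle(m), tolerance = 1e-6)
    expect_equal(prod(f)^(1 / length(f)), 1, tolerance = 1e-10) # geometric mean 1
  }

  # zero-count sample is an error
  tab[1, -1] <- 0
  expect_error(tmm_normalize(tab), "zero total")
})

test_that("sample-SD coverage filter uses population sd and strict boundary", {
  # all samples identical -> sd 0 -> nothing removed
  tab <- random_table(6, 5, rng = function(k) rep(1, k))
  out <- quietly(filter_samples_by_sd(tab, 2))
  expect_identical(nrow(out), 6L)

  # 9 samples with 50 covered genes, 1 with none, x_sd = 2 -> outlier removed
  m <- matrix(1, 10, 50)
  m[10, ] <- 0
  colnames(m) <- paste0("g", 1:50)
  rownames(m) <- paste0("s", 1:10)
  tab <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(as.data.frame(m))
  )
  covered <- rowSums(m > 0)
  mu <- mean(covered)
  sigma <- sqrt(mean((covered - mu)^2))
  expect_true(abs(covered[10] - mu) > 2 * sigma) # oracle arithmetic
  out <- quietly(filter_samples_by_sd(tab, 2))
  expect_identical(out$sample_id, paste0("s", 1:9))
  expect_identical(preprocess_report(out)$samples_removed, "s10")

  # x_sd = 0 removes every off-mean sample (strict inequality)
  tab <- random_table(8, 10, rng = function(k) rbinom(k, 1, 0.5))
  out0 <- quietly(filter_samples_by_sd(tab, 0))
  cov0 <- rowSums(table_matrix(tab) > 0)
  expect_identical(out0$sample_id, tab$sample_id[cov0 == mean(cov0)])
})

test_that("min-value feature filter keeps features over x in >= y samples", {
  # gene at 2.0 in 12 samples passes x=1, y=10
  m <- matrix(0, 15, 3)
  m[1:12, 1] <- 2
  m[1:9, 2] <- 2 # only 9 samples over x -> removed
  m[, 3] <- 1 # never over x = 1 (strict) -> removed
  colnames(m) <- c("kept", "few", "at_x")
  rownames(m) <- paste0("s", 1:15)
  tab <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(as.data.frame(m))
  )
  out <- quietly(filter_features_by_min_value(tab, 1, 10))
  expect_identical(names(out)[-1], "kept")

  # x=0, y=0 is the identity
  tab <- random_table(5, 6)
  expect_identical(
    names(quietly(filter_features_by_min_value(tab, 0, 0))),
    names(tab)
  )

  # brute-force agreement on random tables
  set.seed(21)
  for (i in 1:20) {
    tab <- random_table(5, 12)
    m <- table_matrix(tab)
    x <- sample(0:6, 1)
    y <- sample(0:5, 1)
    keep <- colnames(m)[vapply(
      seq_len(ncol(m)),
      function(j) sum(m[, j] > x) >= y, TRUE
    )]
    out <- quietly(filter_features_by_min_value(tab, x, y))
    expect_identical(names(out)[-1], keep)
  }

  # y above n is legal but warns loudly
  expect_warning(quietly(filter_features_by_min_value(tab, 0, 99)), "exceeds")
})

test_that("taxonomy collapse sums lineages and conserves per-sample totals", {
  tab <- tibble::tibble(
    sample_id = c("s1", "s2"),
    `k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus;s__Species1` = c(5, 1),
    `k__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus;s__Species2` = c(3, 2),
    `k__Bacteria;p__Proteobacteria;c__Gamma;o__Entero;f__Entero;g__Escherichia;s__Species3` = c(1, 7)
  )
  # two species of one genus merge and sum
  out <- quietly(collapse_taxonomy(tab, "g"))
  expect_identical(ncol(out) - 1L, 2L)
  lacto <- grep("g__Lactobacillus", names(out), value = TRUE)
  expect_identical(out[[lacto]], c(8, 3))

  # species rank is identity up to ID truncation
  out_s <- quietly(collapse_taxonomy(tab, "s"))
  expect_identical(ncol(out_s) - 1L, 3L)
  expect_equal(unname(as.matrix(out_s[, -1])), unname(as.matrix(tab[, -1])))

  # conservation of per-sample totals at every rank, unparseable -> unassigned
  tab$bad_lineage <- c(2, 2)
  names(tab)[5] <- "unparseable_string"
  for (rank in c("k", "p", "g")) {
    out_r <- quietly(collapse_taxonomy(tab, rank))
    expect_equal(rowSums(out_r[, -1]), rowSums(tab[, -1]), ignore_attr = TRUE)
    expect_true(any(grepl("unassigned", names(out_r))))
  }
  expect_error(collapse_taxonomy(tab, "x"), "rank")
})

test_that("read-count filters follow the strict '<' boundary and rescale exactly", {
  m <- matrix(c(999, 1000, 1500), 3, 1)
  m <- cbind(m * 0.4, m * 0.6)
  colnames(m) <- c("t1", "t2")
  rownames(m) <- paste0("s", 1:3)
  tab <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(as.data.frame(m))
  )
  out <- quietly(filter_min_reads(tab, 1000)) # 999 < 1000 removed, 1000 kept
  expect_identical(out$sample_id, c("s2", "s3"))
  expect_identical(nrow(quietly(filter_min_reads(tab, 0))), 3L)

  # normalize_reads: every row sums to the target; halving example
  norm <- quietly(normalize_reads(tab, 1000))
  expect_equal(unname(rowSums(norm[, -1])), rep(1000, 3), tolerance = 1e-9)
  half <- quietly(normalize_reads(tab[3, ], 750)) # 1500 -> 750 halves each entry
  expect_equal(unlist(half[, -1]), unlist(tab[3, -1]) / 2, tolerance = 1e-12)
  tab0 <- tab
  tab0[1, -1] <- 0
  expect_error(normalize_reads(tab0, 1000), "zero total")

  # brute-force agreement for min_reads on random tables
  set.seed(31)
  for (i in 1:10) {
    tab <- random_table(8, 5, rng = function(k) rpois(k, 100))
    thr <- sample(400:600, 1)
    keep <- tab$sample_id[rowSums(table_matrix(tab)) >= thr]
    expect_identical(quietly(filter_min_reads(tab, thr))$sample_id, keep)
  }
})

test_that("abundance and prevalence filters match brute-force scans", {
  # column sums {9, 10, 11}, threshold 10 -> only the first removed
  m <- rbind(c(4, 5, 5), c(5, 5, 6))
  colnames(m) <- c("low", "edge", "high")
  rownames(m) <- c("s1", "s2")
  tab <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(as.data.frame(m))
  )
  out <- quietly(filter_abundance(tab, 10))
  expect_identical(names(out)[-1], c("edge", "high"))
  expect_identical(names(quietly(filter_abundance(tab, 0))), names(tab))

  # prevalence: feature in 1 of 50 samples (2%) survives min_prop = 0.01
  m <- matrix(0, 50, 2)
  m[1, 1] <- 5
  colnames(m) <- c("rare", "absent")
  rownames(m) <- paste0("s", 1:50)
  tab <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(as.data.frame(m))
  )
  out <- quietly(filter_prevalence(tab, 0.01))
  expect_identical(names(out)[-1], "rare") # absent feature removed

  set.seed(41)
  for (i in 1:10) {
    tab <- random_table(10, 8, rng = function(k) rbinom(k, 3, 0.2))
    m <- table_matrix(tab)
    thr <- sample(1:6, 1)
    expect_identical(
      names(quietly(filter_abundance(tab, thr)))[-1],
      colnames(m)[colSums(m) >= thr]
    )
    prop <- runif(1, 0, 0.6)
    expect_identical(
      names(quietly(filter_prevalence(tab, prop)))[-1],
      colnames(m)[colSums(m > 0) / nrow(m) >= prop]
    )
  }
})

test_that("metadata-based sample filtering removes the union of rule matches", {
  tab <- random_table(10, 3)
  meta <- tibble::tibble(
    sample_id = tab$sample_id,
    COUNTRY = c(rep("UK", 3), rep("DE", 4), rep("FR", 3)),
    SITE = c(rep("a", 5), rep("b", 5))
  )
  out <- quietly(filter_samples_by_metadata(tab, meta, list(COUNTRY = "UK")))
  expect_identical(nrow(out), 7L)

  # null rules are the identity
  expect_identical(nrow(quietly(filter_samples_by_metadata(tab, meta, NULL))), 10L)

  # two rules on disjoint sets -> union removed
  out2 <- quietly(filter_samples_by_metadata(
    tab, meta,
    list(list(COUNTRY = "UK"), list(SITE = "b"))
  ))
  removed <- union(meta$sample_id[meta$COUNTRY == "UK"], meta$sample_id[meta$SITE == "b"])
  expect_setequal(preprocess_report(out2)$samples_removed, removed)
  expect_error(
    filter_samples_by_metadata(tab, meta, list(REGION = "x")),
    "not found"
  )
})

test_that("class removal and merging rewrite the target correctly", {
  target <- tibble::tibble(
    sample_id = paste0("s", 1:9),
    target = factor(rep(c("A", "B", "C"), each = 3))
  )
  expect_identical(remove_classes(target, character())$target, target)
  out <- remove_classes(target, "C")
  expect_identical(levels(out$target$target), c("A", "B"))
  expect_identical(out$removed, paste0("s", 7:9))
  expect_error(remove_classes(target, c("A", "B", "C")), "no samples")

  merged <- merge_classes(target, list(X = c("A", "B")))
  expect_identical(as.character(merged$target), c(rep("X", 6), rep("C", 3)))
  expect_identical(merge_classes(target, list()), target)
  expect_error(
    merge_classes(target, list(X = "A", Y = c("A", "B"))),
    "ambiguous"
  )
})

test_that("every filter reports a subset of input IDs with exact reconciliation", {
  set.seed(51)
  tab <- random_table(12, 10, rng = function(k) rpois(k, 3))
  meta <- tibble::tibble(sample_id = tab$sample_id, GRP = rep(c("x", "y"), 6))
  filters <- list(
    function(t) filter_samples_by_sd(t, 1),
    function(t) filter_features_by_min_value(t, 2, 3),
    function(t) filter_min_reads(t, 25),
    function(t) filter_abundance(t, 30),
    function(t) filter_prevalence(t, 0.5),
    function(t) filter_samples_by_metadata(t, meta, list(GRP = "x"))
  )
  for (f in filters) {
    out <- quietly(f(tab))
    rep_ <- preprocess_report(out)
    expect_true(all(out$sample_id %in% tab$sample_id))
    expect_true(all(names(out)[-1] %in% names(tab)[-1]))
    # removed + retained reconcile exactly on both axes
    expect_identical(
      sort(c(out$sample_id, rep_$samples_removed)),
      sort(tab$sample_id)
    )
    expect_identical(
      sort(c(names(out)[-1], rep_$features_removed)),
      sort(names(tab)[-1])
    )
  }
})

test_that("the microbiome chain applies filters in the documented order", {
  gen <- make_microbiome_table(n = 30, p = 20, n_informative = 4, seed = 99)
  cfg <- quietly(parse_config(list(
    data_path = "x", metadata_path = "y", target_column = "target",
    problem_type = "classification", data_type = "microbiome",
    collapse_tax = "g", min_reads = 500, norm_reads = 1000,
    filter_abundance = 5, filter_prevalence = 0.1
  )))
  meta <- gen$target
  pre <- quietly(preprocess_omics(gen$table, gen$target, meta, cfg))
  rules <- vapply(pre$reports, function(r) r$rule, "")
  expect_identical(
    rules,
    c(
      "collapse_taxonomy", "filter_min_reads", "normalize_reads",
      "filter_abundance", "filter_prevalence", "filter_samples_by_metadata"
    )
  )
  # table and target stay aligned after the chain
  expect_identical(pre$table$sample_id, pre$target$sample_id)
})

test_that("expression types other than COUNTS pass through unchanged", {
  gen <- make_classification_table(n = 20, p = 10, family = "counts", seed = 3)
  for (et in c("FPKM", "TPM", "OTHER")) {
    cfg <- quietly(parse_config(list(
      data_path = "x", metadata_path = "y", target_column = "target",
      problem_type = "classification", data_type = "gene_expression",
      expression_type = et
    )))
    pre <- quietly(preprocess_omics(gen$table, gen$target, gen$target, cfg))
    expect_equal(pre$table, gen$table, ignore_attr = TRUE)
  }
  cfg <- quietly(parse_config(list(
    data_path = "x", metadata_path = "y", target_column = "target",
    problem_type = "classification", data_type = "gene_expression",
    expression_type = "COUNTS"
  )))
  pre <- quietly(preprocess_omics(gen$table, gen$target, gen$target, cfg))
  expect_false(isTRUE(all.equal(pre$table, gen$table, check.attributes = FALSE)))
})
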