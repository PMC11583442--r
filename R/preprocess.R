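#' Omic-aware pre-processing
#'
#' Optional, data-type-specific filtering and normalisation applied *before*
#' train/test splitting. Every filter returns the filtered table with a
#' `preprocess_report` attribute recording exactly which samples/features the
#' rule removed; [preprocess_report()] retrieves it. Filters only ever drop
#' rows/columns -- output IDs are always a subset of input IDs.
#'
#' @name omics_preprocess
NULL

new_report <- function(rule, samples_removed = character(),
                       features_removed = character(), params = list(),
                       normalization = NULL) {
  structure(
    list(
      rule = rule,
      samples_removed = samples_removed,
      features_removed = features_removed,
      params = params,
      normalization = normalization
    ),
    class = "preprocess_report"
  )
}

attach_report <- function(table, report) {
  n_s <- length(report$samples_removed)
  n_f <- length(report$features_removed)
  message(
    report$rule, ": removed ", n_s, " sample(s), ", n_f,
    " feature(s); retained ", nrow(table), " x ", ncol(table) - 1
  )
  attr(table, "report") <- report
  table
}

#' Retrieve the report attached by a pre-processing filter
#'
#' @param table A feature table returned by one of the `filter_*` /
#'   normalisation functions.
#' @return A `preprocess_report` (rule name, removed sample/feature IDs,
#'   parameters), or `NULL` if none is attached.
#' @export
preprocess_report <- function(table) attr(table, "report")

#' @export
print.preprocess_report <- function(x, ...) {
  cat(
    "<preprocess_report>", x$rule, "-",
    length(x$samples_removed), "sample(s),",
    length(x$features_removed), "feature(s) removed\n"
  )
  invisible(x)
}

#' TMM normalisation of raw counts
#'
#' Converts a table of raw sequencing counts to counts-per-million of the
#' effective (TMM-scaled) library sizes. Per-sample scaling factors follow the
#' trimmed-mean-of-M-values procedure: the reference sample is the one whose
#' upper-quartile is closest to the mean upper-quartile; per pair, M-values
#' (log2 ratios of depth-normalised counts) are double-trimmed (30% on M, 5%
#' on A) and averaged with precision weights; genes with a zero count in
#' either member of a pair are excluded from that pair's mean; factors are
#' rescaled so their geometric mean is 1. Factor computation is delegated to
#' edgeR, the field's canonical implementation.
#'
#' @param table Feature table of non-negative counts (at least 2 samples).
#' @return Feature table of TMM-normalised counts per million, with the
#'   scaling factors in attribute `"norm_factors"` and a report attached.
#' @export
tmm_normalize <- function(table) {
  table <- as_feature_table(table)
  m <- ft_matrix(table)
  if (nrow(m) < 2) stop("TMM needs at least 2 samples", call. = FALSE)
  if (any(m < 0)) stop("TMM requires non-negative counts", call. = FALSE)
  lib <- rowSums(m)
  if (any(lib == 0)) {
    stop("sample(s) with zero total count: ",
      paste(rownames(m)[lib == 0], collapse = ", "),
      call. = FALSE
    )
  }
  # edgeR works genes x samples
  f <- edgeR::calcNormFactors(t(m), method = "TMM")
  eff <- lib * f
  out <- sweep(m, 1, eff, "/") * 1e6
  res <- ft_from_matrix(out)
  attr(res, "norm_factors") <- stats::setNames(f, rownames(m))
  attach_report(res, new_report("tmm_normalize",
    params = list(norm_factors = f),
    normalization = "TMM counts-per-million of effective library sizes"
  ))
}

#' Remove samples whose breadth of coverage is an outlier
#'
#' Counts, per sample, the features with value strictly greater than zero
#' ("with coverage") and removes samples whose count lies more than
#' `x_sd` population standard deviations from the mean count. With a zero
#' standard deviation (all samples identical) nothing is removed.
#'
#' @param table Feature table.
#' @param x_sd Non-negative number of standard deviations.
#' @return Filtered feature table with report.
#' @export
filter_samples_by_sd <- function(table, x_sd) {
  table <- as_feature_table(table)
  stopifnot(is.numeric(x_sd), x_sd >= 0)
  m <- ft_matrix(table)
  covered <- rowSums(m > 0)
  mu <- mean(covered)
  sigma <- sqrt(mean((covered - mu)^2)) # population sd
  drop <- if (sigma == 0) rep(FALSE, nrow(m)) else abs(covered - mu) > x_sd * sigma
  out <- table[!drop, , drop = FALSE]
  attach_report(out, new_report("filter_samples_by_sd",
    samples_removed = rownames(m)[drop],
    params = list(x_sd = x_sd, mean = mu, sd = sigma)
  ))
}

#' Keep features expressed above a value in enough samples
#'
#' Keeps feature `f` iff its value exceeds `x` (strictly) in at least `y`
#' samples; everything else is treated as noise and removed.
#'
#' @param table Feature table.
#' @param x Expression/measurement threshold.
#' @param y Minimum number of samples exceeding `x`.
#' @return Filtered feature table with report.
#' @export
filter_features_by_min_value <- function(table, x, y) {
  table <- as_feature_table(table)
  stopifnot(y >= 0)
  m <- ft_matrix(table)
  if (y > nrow(m)) {
    warning("y (", y, ") exceeds the number of samples (", nrow(m),
      "); every feature will be removed",
      call. = FALSE
    )
  }
  keep <- colSums(m > x) >= y
  out <- table[, c(TRUE, keep), drop = FALSE]
  attach_report(out, new_report("filter_features_by_min_value",
    features_removed = colnames(m)[!keep],
    params = list(x = x, y = y)
  ))
}

RANK_LETTERS <- c("k", "p", "c", "o", "f", "g", "s")

#' Collapse taxonomic features to a higher rank
#'
#' Feature IDs must carry QIIME-style rank-prefixed lineages
#' (`k__...;p__...;c__...` etc.). Features sharing the lineage truncated at
#' the requested rank are summed; lineages that cannot be parsed to that rank
#' are grouped under `"unassigned"`. Per-sample totals are conserved.
#'
#' @param table Feature table with lineage feature IDs.
#' @param rank One of `"k","p","c","o","f","g","s"`.
#' @return Collapsed feature table.
#' @export
collapse_taxonomy <- function(table, rank) {
  table <- as_feature_table(table)
  if (!rank %in% RANK_LETTERS) {
    stop("rank must be one of ", paste(RANK_LETTERS, collapse = ", "), call. = FALSE)
  }
  depth <- match(rank, RANK_LETTERS)
  lineages <- ft_features(table)
  key <- vapply(lineages, function(lin) {
    parts <- stringr::str_split(lin, ";")[[1]]
    parts <- stringr::str_trim(parts)
    prefixes <- substr(parts, 1, 3)
    expected <- paste0(RANK_LETTERS[seq_len(min(depth, length(parts)))], "__")
    if (length(parts) < depth || !all(prefixes[seq_len(depth)] == expected)) {
      return(paste0(RANK_LETTERS[depth], "__unassigned"))
    }
    paste(parts[seq_len(depth)], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  m <- ft_matrix(table)
  groups <- unique(key)
  collapsed <- vapply(
    groups,
    function(g) rowSums(m[, key == g, drop = FALSE]),
    numeric(nrow(m))
  )
  if (nrow(m) == 1) collapsed <- matrix(collapsed, nrow = 1, dimnames = list(rownames(m), groups))
  colnames(collapsed) <- groups
  rownames(collapsed) <- rownames(m)
  out <- ft_from_matrix(collapsed)
  attach_report(out, new_report("collapse_taxonomy",
    params = list(rank = rank, n_in = length(lineages), n_out = length(groups))
  ))
}

#' Remove samples with too few total reads
#'
#' Removes samples whose row sum (total read count) is strictly below
#' `threshold` ("fewer reads than specified").
#'
#' @param table Feature table of counts.
#' @param threshold Minimum total reads (default 1000).
#' @return Filtered feature table with report.
#' @export
filter_min_reads <- function(table, threshold = 1000) {
  table <- as_feature_table(table)
  stopifnot(threshold >= 0)
  m <- ft_matrix(table)
  drop <- rowSums(m) < threshold
  out <- table[!drop, , drop = FALSE]
  attach_report(out, new_report("filter_min_reads",
    samples_removed = rownames(m)[drop],
    params = list(threshold = threshold)
  ))
}

#' Rescale every sample to a common total
#'
#' Each row is scaled so that it sums to `total` reads.
#'
#' @param table Feature table; every row sum must be positive.
#' @param total Target row total (default 1000).
#' @return Rescaled feature table.
#' @export
normalize_reads <- function(table, total = 1000) {
  table <- as_feature_table(table)
  m <- ft_matrix(table)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    stop("cannot rescale sample(s) with zero total: ",
      paste(rownames(m)[rs <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  out <- ft_from_matrix(sweep(m, 1, total / rs, "*"))
  attach_report(out, new_report("normalize_reads",
    params = list(total = total),
    normalization = paste("rows rescaled to sum", total)
  ))
}

#' Remove features with low total abundance
#'
#' Removes features whose total across all samples is strictly less than
#' `min_total`.
#'
#' @param table Feature table.
#' @param min_total Minimum total abundance (default 10).
#' @return Filtered feature table with report.
#' @export
filter_abundance <- function(table, min_total = 10) {
  table <- as_feature_table(table)
  m <- ft_matrix(table)
  keep <- colSums(m) >= min_total
  out <- table[, c(TRUE, keep), drop = FALSE]
  attach_report(out, new_report("filter_abundance",
    features_removed = colnames(m)[!keep],
    params = list(min_total = min_total)
  ))
}

#' Remove features observed in too few samples
#'
#' Keeps a feature iff the proportion of samples in which it is observed
#' (value strictly greater than 0) is at least `min_prop`.
#'
#' @param table Feature table.
#' @param min_prop Minimum prevalence as a proportion in \[0, 1\]
#'   (default 0.01).
#' @return Filtered feature table with report.
#' @export
filter_prevalence <- function(table, min_prop = 0.01) {
  table <- as_feature_table(table)
  stopifnot(min_prop >= 0, min_prop <= 1)
  m <- ft_matrix(table)
  keep <- colSums(m > 0) / nrow(m) >= min_prop
  out <- table[, c(TRUE, keep), drop = FALSE]
  attach_report(out, new_report("filter_prevalence",
    features_removed = colnames(m)[!keep],
    params = list(min_prop = min_prop)
  ))
}

#' Remove samples matching metadata categories
#'
#' Each rule is a named single-element list/character, e.g.
#' `list(COUNTRY = "UK")`: every sample whose metadata value in that column
#' equals the category is removed. A sample matching *any* rule is removed;
#' `NULL` rules are the identity.
#'
#' @param table Feature table.
#' @param metadata Metadata tibble (first column `sample_id`).
#' @param rules A list of named rules, or `NULL`.
#' @return Filtered feature table with report.
#' @export
filter_samples_by_metadata <- function(table, metadata, rules = NULL) {
  table <- as_feature_table(table)
  if (is.null(rules) || !length(rules)) {
    return(attach_report(table, new_report("filter_samples_by_metadata",
      params = list(rules = NULL)
    )))
  }
  if (!is.list(rules[[1]]) && !is.null(names(rules))) rules <- list(rules)
  hit <- character()
  for (rule in rules) {
    col <- names(rule)[1]
    if (is.na(col) || !col %in% names(metadata)) {
      stop("metadata filter column '", col, "' not found", call. = FALSE)
    }
    val <- as.character(rule[[1]])
    hit <- union(hit, metadata[[ID_COL]][as.character(metadata[[col]]) == val])
  }
  drop <- table[[ID_COL]] %in% hit
  out <- table[!drop, , drop = FALSE]
  attach_report(out, new_report("filter_samples_by_metadata",
    samples_removed = table[[ID_COL]][drop],
    params = list(rules = rules)
  ))
}

#' Drop target classes
#'
#' Removes every sample whose target label is in `labels`; the feature table
#' is realigned by the caller (see [align_samples()]).
#'
#' @param target Target tibble (`sample_id`, `target` factor).
#' @param labels Character vector of class labels to remove (may be empty).
#' @return A list with `target` (filtered) and `removed` (sample IDs).
#' @export
remove_classes <- function(target, labels) {
  if (is.null(labels) || !length(labels)) {
    return(list(target = target, removed = character()))
  }
  drop <- as.character(target$target) %in% labels
  out <- target[!drop, , drop = FALSE]
  if (!nrow(out)) stop("removing classes ", paste(labels, collapse = ", "),
      " leaves no samples", call. = FALSE)
  out$target <- droplevels(factor(out$target))
  if (nlevels(out$target) < 2) {
    stop("fewer than 2 classes remain after remove_classes", call. = FALSE)
  }
  list(target = out, removed = target$sample_id[drop])
}

#' Merge target classes
#'
#' `mapping` maps each new label to the old labels it absorbs, e.g.
#' `list(X = c("A", "B"))` rewrites labels A and B to X. Unlisted labels are
#' untouched; a label listed under two new labels is an error.
#'
#' @param target Target tibble (`sample_id`, `target` factor).
#' @param mapping Named list: new label -> character vector of old labels.
#' @return The target tibble with rewritten labels.
#' @export
merge_classes <- function(target, mapping) {
  if (is.null(mapping) || !length(mapping)) {
    return(target)
  }
  old <- unlist(mapping, use.names = FALSE)
  if (anyDuplicated(old)) {
    stop("ambiguous merge_classes mapping: label(s) ",
      paste(unique(old[duplicated(old)]), collapse = ", "),
      " appear in more than one group",
      call. = FALSE
    )
  }
  lab <- as.character(target$target)
  for (new in names(mapping)) lab[lab %in% mapping[[new]]] <- new
  target$target <- factor(lab)
  target
}

#' Run the data-type-specific pre-processing chain
#'
#' Applies the filters configured for the run's `data_type`, in a fixed,
#' reproducible order. Gene expression: TMM conversion when
#' `expression_type = "COUNTS"` (all other expression types pass through
#' unchanged), then sample-SD and min-value filters. Microbiome:
#' taxonomy collapse, min-reads, read normalisation, abundance, prevalence,
#' metadata filters, then class removal/merging. Metabolomic/tabular:
#' sample-SD and min-value filters. `data_type = "none"` is the identity.
#'
#' @param table Feature table.
#' @param target Target tibble.
#' @param metadata Full metadata tibble.
#' @param config A run configuration (see [parse_config()]).
#' @return List with `table`, `target`, and `reports` (list of
#'   `preprocess_report`s in application order).
#' @export
preprocess_omics <- function(table, target, metadata, config) {
  reports <- list()
  grab <- function(tab) {
    reports[[length(reports) + 1]] <<- preprocess_report(tab)
    tab
  }
  dt <- config$data_type
  if (dt == "gene_expression") {
    if (identical(config$expression_type, "COUNTS")) table <- grab(tmm_normalize(table))
    if (!is.null(config$filter_sample_sd)) {
      table <- grab(filter_samples_by_sd(table, config$filter_sample_sd))
    }
    if (!is.null(config$filter_feature_min)) {
      table <- grab(filter_features_by_min_value(
        table,
        config$filter_feature_min$value, config$filter_feature_min$samples
      ))
    }
  } else if (dt == "microbiome") {
    if (!is.null(config$collapse_tax)) table <- grab(collapse_taxonomy(table, config$collapse_tax))
    table <- grab(filter_min_reads(table, config$min_reads))
    table <- grab(normalize_reads(table, config$norm_reads))
    table <- grab(filter_abundance(table, config$filter_abundance))
    table <- grab(filter_prevalence(table, config$filter_prevalence))
    table <- grab(filter_samples_by_metadata(table, metadata, config$filter_microbiome_samples))
  } else if (dt %in% c("metabolomic", "tabular")) {
    if (!is.null(config$filter_sample_sd)) {
      table <- grab(filter_samples_by_sd(table, config$filter_sample_sd))
    }
    if (!is.null(config$filter_feature_min)) {
      table <- grab(filter_features_by_min_value(
        table,
        config$filter_feature_min$value, config$filter_feature_min$samples
      ))
    }
  }
  if (config$problem_type == "classification") {
    rc <- remove_classes(target, config$remove_classes)
    target <- rc$target
    target <- merge_classes(target, config$merge_classes)
  }
  aligned <- align_samples(table, target)
  list(table = aligned$table, target = aligned$target, reports = reports)
}
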