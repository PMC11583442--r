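#' Feature tables
#'
#' Throughout omicsml a *feature table* is a tibble whose first column holds
#' unique sample identifiers and whose remaining columns are numeric feature
#' measurements (gene-expression values, taxon abundances, genotype dosages,
#' metabolite intensities, ...). Samples are rows, features are columns --
#' a transposed table is an error, never auto-detected, because silent
#' transposition is a classic omics bug.
#'
#' @name feature_table
#' @keywords internal
NULL

ID_COL <- "sample_id"

#' Validate a data frame as a feature table
#'
#' Checks the feature-table contract: first column = unique sample IDs, all
#' other columns numeric and finite (missing values are an error, not
#' silently imputed), unique feature names.
#'
#' @param x A data frame; first column sample IDs, remaining columns numeric.
#' @return A tibble satisfying the contract, with the ID column renamed to
#'   `sample_id`.
#' @export
as_feature_table <- function(x) {
  if (!is.data.frame(x)) {
    stop("a feature table must be a data frame (samples in rows)", call. = FALSE)
  }
  if (ncol(x) < 2) stop("a feature table needs at least one feature column", call. = FALSE)
  x <- tibble::as_tibble(x)
  ids <- as.character(x[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicated sample ID(s): ", paste(utils::head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  feats <- names(x)[-1]
  if (anyDuplicated(feats)) {
    dup <- unique(feats[duplicated(feats)])
    stop("duplicated feature ID(s): ", paste(utils::head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  for (j in seq_along(feats)) {
    col <- x[[j + 1L]]
    if (!is.numeric(col)) {
      stop("non-numeric values in feature '", feats[j],
        "'; categorical features must be one-hot encoded before loading",
        call. = FALSE
      )
    }
    bad <- which(!is.finite(col))
    if (length(bad)) {
      stop("non-finite value in feature '", feats[j], "', sample '",
        ids[bad[1]], "'; missing entries are rejected, not imputed",
        call. = FALSE
      )
    }
  }
  names(x)[1] <- ID_COL
  x[[1]] <- ids
  x
}

#' Read a samples-by-features CSV
#'
#' The file must have a header row of feature names and a first column of
#' sample identifiers. Values must be numeric and complete; any non-numeric
#' or missing cell is an error naming the offending row and column.
#'
#' @param path Path to a CSV file.
#' @return A feature table tibble (see [as_feature_table()]).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(sample = c("s1", "s2"), g1 = 1:2, g2 = c(3.5, 4)),
#'   tf,
#'   row.names = FALSE
#' )
#' read_feature_table(tf)
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = NA
  )
  if (ncol(raw) < 2) stop("expected sample IDs plus at least one feature column", call. = FALSE)
  ids <- as.character(raw[[1]])
  for (j in 2:ncol(raw)) {
    col <- raw[[j]]
    if (is.character(col) || anyNA(suppressWarnings(as.numeric(col)))) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num))[1]
      stop(
        "non-numeric or missing cell at sample '", ids[bad], "', feature '",
        names(raw)[j], "' in ", basename(path),
        call. = FALSE
      )
    }
  }
  as_feature_table(raw)
}

#' Read a metadata table
#'
#' Metadata rows are samples; the first column holds sample identifiers.
#' Other columns may be any type (the target column is extracted later).
#'
#' @param path Path to a CSV file.
#' @return A tibble with first column `sample_id`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- tibble::as_tibble(utils::read.csv(path,
    check.names = FALSE,
    stringsAsFactors = FALSE
  ))
  if (ncol(x) < 2) stop("metadata needs sample IDs plus at least one column", call. = FALSE)
  ids <- as.character(x[[1]])
  if (anyDuplicated(ids)) stop("duplicated sample ID(s) in metadata", call. = FALSE)
  names(x)[1] <- ID_COL
  x[[1]] <- ids
  x
}

#' Extract the prediction target from metadata
#'
#' @param metadata A metadata tibble (see [read_metadata()]).
#' @param target_column Name of the column to predict.
#' @param problem_type `"classification"` or `"regression"`.
#' @return A tibble with columns `sample_id` and `target` (factor for
#'   classification, numeric for regression).
#' @export
extract_target <- function(metadata, target_column,
                           problem_type = c("classification", "regression")) {
  problem_type <- match.arg(problem_type)
  if (!target_column %in% names(metadata)) {
    stop("target column '", target_column, "' absent from metadata", call. = FALSE)
  }
  vals <- metadata[[target_column]]
  if (anyNA(vals)) stop("missing values in target column '", target_column, "'", call. = FALSE)
  if (problem_type == "classification") {
    vals <- factor(as.character(vals))
    if (nlevels(vals) < 2) {
      stop("classification needs at least 2 distinct classes in '",
        target_column, "'",
        call. = FALSE
      )
    }
  } else {
    vals <- suppressWarnings(as.numeric(vals))
    if (anyNA(vals)) stop("target column '", target_column, "' is not numeric", call. = FALSE)
  }
  tibble::tibble(sample_id = metadata[[ID_COL]], target = vals)
}

#' Align a feature table and a target on shared samples
#'
#' Both are restricted to the intersection of their sample IDs, in the feature
#' table's order; the number of dropped samples is reported via `message()`.
#' Alignment is idempotent.
#'
#' @param table A feature table.
#' @param target A target tibble (`sample_id`, `target`) or metadata tibble.
#' @return A list with elements `table` and `target`, row-aligned.
#' @export
align_samples <- function(table, target) {
  table <- as_feature_table(table)
  shared <- intersect(table[[ID_COL]], target[[ID_COL]])
  if (!length(shared)) stop("no shared sample IDs between data and metadata", call. = FALSE)
  dropped <- (nrow(table) - length(shared)) + (nrow(target) - length(shared))
  if (dropped > 0) {
    message("align_samples: dropped ", dropped, " unmatched row(s); ",
      length(shared), " sample(s) retained")
  }
  table <- table[match(shared, table[[ID_COL]]), , drop = FALSE]
  target <- target[match(shared, target[[ID_COL]]), , drop = FALSE]
  if (is.factor(target$target)) target$target <- droplevels(target$target)
  list(table = table, target = target)
}

#' Encode diploid genotype calls as numeric dosages
#'
#' Converts categorical calls to the ordinal coding in which the value grows
#' with the number of alternate alleles: hom-ref = 0, het = 1, hom-alt = 2,
#' missing = 3. `invert = TRUE` gives the reversed coding
#' (hom-ref = 2, het = 1, hom-alt = 0, missing = 3) used by some genotyping
#' pipelines; both are supported, neither is asserted as canonical.
#'
#' @param calls A data frame (first column sample IDs) or character matrix of
#'   tokens `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.
#' @param invert Use the reversed ref=2 ... alt=0 coding.
#' @return A feature table tibble of numeric dosages.
#' @export
encode_genotypes <- function(calls, invert = FALSE) {
  if (is.matrix(calls)) {
    ids <- rownames(calls)
    if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(calls)))
    calls <- tibble::as_tibble(as.data.frame(calls, stringsAsFactors = FALSE))
    calls <- dplyr::bind_cols(tibble::tibble(sample_id = ids), calls)
  }
  calls <- tibble::as_tibble(calls)
  code <- c(hom_ref = 0, het = 1, hom_alt = 2, missing = 3)
  if (invert) code <- c(hom_ref = 2, het = 1, hom_alt = 0, missing = 3)
  out <- calls
  for (j in 2:ncol(calls)) {
    tok <- as.character(calls[[j]])
    bad <- setdiff(unique(tok), names(code))
    if (length(bad)) {
      stop("unrecognized genotype call token(s) in '", names(calls)[j], "': ",
        paste(utils::head(bad, 5), collapse = ", "),
        call. = FALSE
      )
    }
    out[[j]] <- unname(code[tok])
  }
  as_feature_table(out)
}

# internal: tibble <-> matrix
ft_matrix <- function(table) {
  m <- as.matrix(table[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table[[ID_COL]]
  m
}

ft_from_matrix <- function(m) {
  tibble::as_tibble(as.data.frame(m, check.names = FALSE),
    .name_repair = "minimal"
  ) |>
    (\(x) dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), x))()
}

ft_features <- function(table) names(table)[-1]
ft_samples <- function(table) table[[ID_COL]]
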