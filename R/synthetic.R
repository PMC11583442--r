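#' Synthetic omics fixtures with planted signal
#'
#' Seeded generators emulating the tabular input families the pipeline
#' consumes: negative-binomial expression counts, compositional microbiome
#' abundances (Dirichlet-multinomial with log-normal library sizes, so
#' read-count and prevalence filters have realistic work to do), 0-2
#' genotype dosages under Hardy-Weinberg sampling, and plain Gaussian
#' tabular data. A subset of features carries planted signal of a stated
#' effect size; the ground truth (which features, which direction) is
#' returned so tests can check signal recovery. Generators are pure
#' functions of their arguments: the same seed reproduces the same table
#' bit-for-bit.
#'
#' @name synthetic_fixtures
NULL

feature_names <- function(p, family) {
  prefix <- switch(family,
    counts = "gene",
    abundance = "taxon",
    genotype = "snp",
    gaussian = "feat"
  )
  sprintf("%s_%04d", prefix, seq_len(p))
}

draw_family_matrix <- function(n, p, family, shift) {
  # `shift` is an n x p matrix of per-cell signal on the family's natural scale
  if (family == "counts") {
    mu <- exp(log(100) + matrix(stats::rnorm(n * p, 0, 0.5), n, p) + shift)
    matrix(stats::rnbinom(n * p, mu = mu, size = 4), n, p)
  } else if (family == "abundance") {
    alpha0 <- exp(stats::rnorm(p, 0, 1.2)) # skewed base composition
    lib <- round(stats::rlnorm(n, log(2e4), 0.35))
    t(vapply(seq_len(n), function(i) {
      a <- alpha0 * exp(shift[i, ])
      w <- stats::rgamma(p, shape = a * 0.5, rate = 1) # Dirichlet draw
      w <- w / sum(w)
      as.numeric(stats::rmultinom(1, lib[i], w))
    }, numeric(p)))
  } else if (family == "genotype") {
    maf <- stats::runif(p, 0.1, 0.5)
    t(vapply(seq_len(n), function(i) {
      pa <- pmin(pmax(maf + shift[i, ], 0.02), 0.98)
      stats::rbinom(p, 2, pa)
    }, numeric(p)))
  } else {
    matrix(stats::rnorm(n * p), n, p) + shift
  }
}

family_effect_scale <- function(family) {
  # planted shift per unit effect, on each family's natural scale
  switch(family,
    counts = 0.5, # NB log-mean shift
    abundance = 0.75, # log-concentration shift
    genotype = 0.12, # allele-frequency shift
    gaussian = 0.5
  )
}

#' Synthetic classification table
#'
#' Balanced class assignments; the informative features are shifted between
#' classes by `effect` (interpreted on the family's natural scale: log-mean
#' shift for counts, log-concentration shift for abundances, allele-frequency
#' shift for genotypes, mean shift in units of the noise SD for Gaussian
#' data). Null features are exchangeable across classes.
#'
#' @param n,p Number of samples and features.
#' @param n_informative Number of features carrying planted signal.
#' @param effect Effect size (e.g. Cohen's d for the Gaussian family).
#' @param family `"gaussian"`, `"counts"`, `"abundance"`, or `"genotype"`.
#' @param n_classes Number of classes (default 2).
#' @param seed Integer seed.
#' @return List: `table` (feature table), `target` (tibble), `truth`
#'   (informative IDs, per-feature signed effects, family, seed).
#' @export
make_classification_table <- function(n = 100, p = 50, n_informative = 10,
                                      effect = 2, family = "gaussian",
                                      n_classes = 2, seed = 42) {
  stopifnot(n_informative <= p, n_classes >= 2)
  with_seed(seed, {
    y <- factor(rep_len(paste0("class_", seq_len(n_classes)), n))
    informative <- if (n_informative > 0) sort(sample.int(p, n_informative)) else integer()
    signs <- sample(c(-1, 1), n_informative, replace = TRUE)
    shift <- matrix(0, n, p)
    if (n_informative > 0) {
      class_pattern <- matrix(
        stats::rnorm(n_classes * n_informative), n_classes, n_informative
      )
      class_pattern <- scale(class_pattern, center = TRUE, scale = FALSE) # centre per feature
      if (n_classes == 2) class_pattern <- matrix(c(-0.5, 0.5), 2, n_informative)
      sc <- family_effect_scale(family) * effect
      for (j in seq_len(n_informative)) {
        shift[, informative[j]] <- sc * signs[j] * class_pattern[as.integer(y), j]
      }
    }
    m <- draw_family_matrix(n, p, family, shift)
    colnames(m) <- feature_names(p, family)
    rownames(m) <- sprintf("sample_%03d", seq_len(n))
    list(
      table = ft_from_matrix(m),
      target = tibble::tibble(sample_id = rownames(m), target = y),
      truth = list(
        informative = colnames(m)[informative],
        effects = stats::setNames(signs * effect, colnames(m)[informative]),
        family = family, n_classes = n_classes, seed = seed
      )
    )
  })
}

#' Synthetic regression table
#'
#' The target is a linear combination of the informative features plus
#' Gaussian noise. The generator reports the planted population R-squared
#' computed from the coefficients and noise variance.
#'
#' @param n,p Number of samples and features.
#' @param n_informative Number of contributing features.
#' @param coef_scale Scale of the (signed) true coefficients.
#' @param noise_sd Noise standard deviation; `r2_target` may be given
#'   instead, in which case `noise_sd` is derived to plant that R-squared.
#' @param family Feature family (as in [make_classification_table()]).
#' @param r2_target Optional planted population R-squared in (0, 1).
#' @param seed Integer seed.
#' @return List: `table`, `target`, `truth` (coefficients, noise SD,
#'   planted R-squared).
#' @export
make_regression_table <- function(n = 100, p = 50, n_informative = 10,
                                  coef_scale = 1, noise_sd = 1,
                                  family = "gaussian", r2_target = NULL,
                                  seed = 42) {
  stopifnot(n_informative <= p)
  with_seed(seed, {
    m <- draw_family_matrix(n, p, family, matrix(0, n, p))
    colnames(m) <- feature_names(p, family)
    rownames(m) <- sprintf("sample_%03d", seq_len(n))
    informative <- sort(sample.int(p, n_informative))
    beta <- stats::setNames(
      coef_scale * sample(c(-1, 1), n_informative, TRUE) *
        stats::runif(n_informative, 0.5, 1.5),
      colnames(m)[informative]
    )
    Xi <- scale(m[, informative, drop = FALSE])
    Xi[is.nan(Xi)] <- 0
    signal <- as.numeric(Xi %*% beta)
    var_signal <- stats::var(signal)
    if (!is.null(r2_target)) {
      stopifnot(r2_target > 0, r2_target < 1)
      noise_sd <- sqrt(var_signal * (1 - r2_target) / r2_target)
    }
    y <- signal + stats::rnorm(n, 0, noise_sd)
    planted_r2 <- if (coef_scale == 0) 0 else var_signal / (var_signal + noise_sd^2)
    list(
      table = ft_from_matrix(m),
      target = tibble::tibble(sample_id = rownames(m), target = y),
      truth = list(
        informative = colnames(m)[informative], coefficients = beta,
        noise_sd = noise_sd, planted_r2 = planted_r2, family = family,
        seed = seed
      )
    )
  })
}

#' Synthetic diploid genotype calls
#'
#' Per feature, an allele frequency is drawn from `maf_range` and genotypes
#' sampled under Hardy-Weinberg proportions; entries are set to missing at
#' the stated rate. Output tokens are those [encode_genotypes()] accepts.
#'
#' @param n,p Number of samples and markers.
#' @param maf_range Range of minor-allele frequencies.
#' @param missing_rate Probability an entry is missing.
#' @param seed Integer seed.
#' @return A tibble (first column `sample_id`) of call tokens.
#' @export
make_genotype_calls <- function(n = 50, p = 20, maf_range = c(0.05, 0.5),
                                missing_rate = 0, seed = 42) {
  with_seed(seed, {
    maf <- stats::runif(p, maf_range[1], maf_range[2])
    tokens <- c("hom_ref", "het", "hom_alt")
    m <- vapply(seq_len(p), function(j) {
      g <- stats::rbinom(n, 2, maf[j]) + 1L
      calls <- tokens[g]
      if (missing_rate > 0) {
        calls[stats::runif(n) < missing_rate] <- "missing"
      }
      calls
    }, character(n))
    colnames(m) <- sprintf("snp_%04d", seq_len(p))
    df <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("sample_%03d", seq_len(n))), df
    )
  })
}

#' Synthetic microbiome table with QIIME-style lineages
#'
#' Convenience wrapper around the `"abundance"` family that renames features
#' to rank-prefixed lineages (`k__...;p__...;g__...;s__...`) so taxonomy
#' collapsing is exercised realistically.
#'
#' @inheritParams make_classification_table
#' @param n_genera Number of genera the species are nested under.
#' @return As [make_classification_table()].
#' @export
make_microbiome_table <- function(n = 60, p = 40, n_informative = 8,
                                  effect = 2, n_classes = 2, n_genera = 12,
                                  seed = 42) {
  out <- make_classification_table(
    n, p, n_informative, effect,
    family = "abundance", n_classes = n_classes, seed = seed
  )
  lineages <- with_seed(derive_seed(seed, 5), {
    genus <- sample.int(n_genera, p, replace = TRUE)
    sprintf(
      "k__Bacteria;p__Phylum%02d;c__Class%02d;o__Order%02d;f__Family%02d;g__Genus%02d;s__Species%04d",
      (genus - 1) %% 4 + 1, (genus - 1) %% 6 + 1, (genus - 1) %% 8 + 1,
      genus, genus, seq_len(p)
    )
  })
  rename_map <- stats::setNames(ft_features(out$table), lineages)
  names(out$table) <- c("sample_id", lineages)
  out$truth$informative <- lineages[match(out$truth$informative, unname(rename_map))]
  names(out$truth$effects) <- lineages[match(names(out$truth$effects), unname(rename_map))]
  out
}
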