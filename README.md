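# omicsml

Automated, explainable machine learning for omics and numeric tabular data.

## The problem

A recurring task across transcriptomics, metagenomics, genomics and
metabolomics is supervised prediction from a samples × features table:
classify infection state from gene expression, predict a phenotype from SNP
dosages, regress soil pH on species abundances. Doing this well involves a
long chain of decisions — omic-appropriate filtering and normalisation, a
leak-free train/test split, feature scaling, how many features to keep,
class rebalancing, which learners to tune and how, which tuned model to
trust, and how to read biology out of the winner. `omicsml` automates that
chain behind a single JSON configuration, for users who want robust,
interpretable models without hand-building the pipeline each time.

A run executes, in order:

1. **Load + omic pre-processing.** Gene-expression counts are converted to
   TMM-normalised counts per million (trimmed mean of M-values: per-library
   scaling factors from a doubly trimmed — 30% on M = log2 expression ratio,
   5% on A = mean log2 abundance — precision-weighted mean against a
   reference sample, rescaled to geometric mean 1). Microbiome tables get
   taxonomy collapsing (QIIME-style `k__...;p__...` lineages), minimum-read
   and read-rescaling filters (defaults 1000), total-abundance (default 10)
   and prevalence (default 0.01) filters, and metadata-based sample removal.
   Expression/metabolomic/tabular data get coverage-outlier and
   minimum-value filters. Every filter logs exactly what it removed.
2. **Split + standardise.** Stratified train/test split (default 80:20,
   seeded). Each feature is mapped through its *training-set* empirical CDF
   to [0, 1] (quantile transformation — robust to the skewed marginals of
   omics data); the test partition never touches any fitted parameter.
3. **Feature selection.** Variance thresholding, then univariate scoring
   (one-way ANOVA F for classification, univariate regression
   F = r²/(1−r²)·(n−2) for regression) and k-best selection. With
   `k = "auto"`, ~10 log-spaced candidate ks are each scored by 5-fold CV of
   a default random forest, and the chosen k is the largest member of the
   best-performing, most stable window of three consecutive candidates
   (maximising mean − sd of the window scores) — a lone spiked k with poor
   neighbours is deliberately not trusted.
4. **Balancing (optional).** Random over- or under-sampling of the training
   partition only.
5. **Tune + evaluate.** A registry of classical learners — random forest,
   gradient-boosted trees, AdaBoost, k-nearest neighbours, and a
   histogram-binned (LightGBM-style) booster, all built on the package's
   compiled CART engine — tuned by grid/random/no search under seeded
   5-fold CV, then scored on train and test with the full metric panel
   (accuracy, precision, F1, one-vs-rest AUC; MSE, MAE, MAPE, R²).
6. **Best-model recommendation.** Each model is a point (train, test) of the
   scoring metric; the winner minimises
   `D = √((t−i)² + (v−i)²) + |t−v|/√2`, distance to the ideal corner
   (i = 1 for score metrics, 0 for error metrics) plus distance to the
   train = test diagonal — so an overfit model with a flattering training
   score loses to a balanced one. Ties are noted in a text file.
7. **Explanations.** Exact tree-path Shapley attributions (per class, with
   `base + Σ attributions = model output` to machine precision) and
   permutation importances, exported as
   `shapley_values_all_[Model_Class].csv` and
   `permutimp_TopFeatures_info_[Model].csv`, plus global bar/dot plot data.

Four run modes reuse one persisted bundle: `train`, `plot` (regenerate
figures), `holdout` (evaluate on new labelled data), `predict` (score
unlabelled data, with explanations).

## Worked example

A small synthetic RNA-seq-like fixture ships with the package (30 samples ×
40 genes of negative-binomial counts, 6 genes differentially expressed
between `control` and `treated`):

```r
library(omicsml)

counts <- read_feature_table(system.file("extdata", "synthetic_expression_counts.csv", package = "omicsml"))
meta   <- read_metadata(system.file("extdata", "synthetic_expression_metadata.csv", package = "omicsml"))

cfg <- parse_config(list(
  data_path = "unused", metadata_path = "unused",
  target_column = "condition", problem_type = "classification",
  data_type = "gene_expression", expression_type = "COUNTS",
  models = c("rf", "knn"), hyper_tuning = "none", seed = 7,
  feature_selection = list(k = 10)
))
run <- run_training(cfg, output_dir = "my_run", table = counts, target = meta)
run
#> <oml_run> classification | 24 train / 6 test | 10 features | 2 models
#> best model: rf ( f1 test = 1 )

glance(run)
#> # A tibble: 2 × 9
#>   model scoring train cv_mean  cv_sd  test n_candidates      D best
#>   <chr> <chr>   <dbl>   <dbl>  <dbl> <dbl>        <int>  <dbl> <lgl>
#> 1 rf    f1       1      0.971 0.0639     1            1 0      TRUE
#> 2 knn   f1       0.96   0.943 0.0782     1            1 0.0683 FALSE

head(run$explanations$ranking, 5)
#> # A tibble: 5 × 2
#>   feature   mean_abs_attribution
#>   <chr>                    <dbl>
#> 1 gene_0017               0.234
#> 2 gene_0006               0.218
#> 3 gene_0023               0.113
#> 4 gene_0016               0.0910
#> 5 gene_0029               0.0797
```

Reading the output: the raw counts were TMM-normalised, 10 genes kept by
ANOVA-F selection, and both learners cross-validated. The random forest sits
closer to the ideal corner of the train/test plane (`D = 0`: train and test
F1 both 1), so it is recommended; the attribution ranking puts truly
differential genes (here `gene_0017`, `gene_0006`, ...) at the top, which is
how the tool is meant to be used as a hypothesis generator. `my_run/`
contains the results table, the Shapley and permutation-importance CSVs, the
`best_model/` folder and the reusable bundle. `tidy(run)` returns the full
per-model, per-metric table; `autoplot(run)` draws the recommendation plane.

The same workflow runs from a shell via the bundled wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "omicsml.R", package = "omicsml"))') \
  train --config config.json --output my_run
```

with `plot`, `holdout` and `predict` subcommands operating on `my_run`. The
accepted configuration keys are documented in
`inst/extdata/config-schema.json`;
`inst/extdata/synthetic_expression_config.json` is a complete example.

## Synthetic data

`make_classification_table()`, `make_regression_table()`,
`make_genotype_calls()` and `make_microbiome_table()` generate seeded tables
with planted, known signal in four families (negative-binomial counts,
Dirichlet-multinomial compositions with log-normal library sizes,
Hardy-Weinberg genotype dosages, Gaussian), used throughout the test suite
so every pipeline stage is verifiable without downloads.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
on seeded synthetic data — a full classification training run (automated-k
feature selection, the whole model registry, best-model recommendation,
explanations) and a full regression run with random hyperparameter search —
and writes its JSON result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
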