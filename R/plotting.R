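#' Plot suite
#'
#' Every plot is rendered from a run bundle as a PNG *plus a companion CSV
#' of the plotted numbers* (same basename), so tests and downstream analyses
#' work with data, not pixels. Supported names: `cv_box`, `metric_bar`,
#' `confusion`, `roc`, `selection_curve`, `correlation`, `joint`,
#' `shap_bar`, `shap_dot`, `permutation_bar`. An empty plot list is a no-op.
#'
#' @name plotting
NULL

CLASSIFICATION_PLOTS <- c("confusion", "roc")
REGRESSION_PLOTS <- c("correlation", "joint")

roc_points <- function(is_pos, score) {
  ord <- order(-score)
  tp <- cumsum(is_pos[ord])
  fp <- cumsum(!is_pos[ord])
  keep <- !duplicated(score[ord], fromLast = TRUE)
  tibble::tibble(
    fpr = c(0, fp[keep] / max(sum(!is_pos), 1)),
    tpr = c(0, tp[keep] / max(sum(is_pos), 1))
  )
}

plot_data <- function(run, name) {
  scoring <- run$config$scoring
  best <- run$results[[run$best$winner]]
  switch(name,
    cv_box = purrr::map_dfr(run$results, function(r) {
      tibble::tibble(
        model = r$name, fold = seq_along(r$cv_scores),
        score = r$cv_scores, metric = scoring
      )
    }),
    metric_bar = purrr::map_dfr(run$results, function(r) {
      tibble::tibble(
        model = r$name, metric = scoring,
        test = unname(r$test_metrics[[scoring]])
      )
    }),
    confusion = {
      pred <- best$predictions$test$pred
      truth <- run$data$y_test
      tibble::as_tibble(as.data.frame(table(truth = truth, predicted = pred),
        stringsAsFactors = FALSE
      )) |>
        dplyr::rename(n = "Freq")
    },
    roc = {
      prob <- best$predictions$test$prob
      truth <- run$data$y_test
      purrr::map_dfr(levels(truth), function(lv) {
        dplyr::mutate(roc_points(truth == lv, prob[, lv]), class = lv, .before = 1)
      })
    },
    selection_curve = {
      if (is.null(run$selection_curve)) {
        stop("no feature-selection curve in this run (k was not 'auto')", call. = FALSE)
      }
      tibble::as_tibble(run$selection_curve)
    },
    correlation = ,
    joint = tibble::tibble(
      true = run$data$y_test,
      predicted = best$predictions$test$pred
    ),
    shap_bar = run$explanations$ranking,
    shap_dot = {
      top <- run$explanations$ranking$feature
      dplyr::filter(tidy(run$explanations), .data$feature %in% top)
    },
    permutation_bar = dplyr::arrange(run$permimp, dplyr::desc(.data$importance)),
    stop("unknown plot '", name, "'", call. = FALSE)
  )
}

plot_figure <- function(run, name, data) {
  scoring <- run$config$scoring
  best_name <- run$best$winner
  switch(name,
    cv_box = ggplot2::ggplot(data, ggplot2::aes(x = .data$model, y = .data$score)) +
      ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
      ggplot2::labs(y = paste("CV", scoring), x = NULL, title = "Cross-validation performance"),
    metric_bar = ggplot2::ggplot(data, ggplot2::aes(x = .data$model, y = .data$test)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(y = paste("test", scoring), x = NULL, title = "Held-out test performance"),
    confusion = ggplot2::ggplot(data, ggplot2::aes(.data$predicted, .data$truth, fill = .data$n)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
      ggplot2::labs(title = paste("Confusion matrix -", best_name)),
    roc = ggplot2::ggplot(data, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$class)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = "dotted") +
      ggplot2::labs(
        x = "false positive rate", y = "true positive rate",
        title = paste("One-vs-rest ROC -", best_name)
      ),
    selection_curve = autoplot.oml_selection_curve(run$selection_curve),
    correlation = ggplot2::ggplot(data, ggplot2::aes(.data$true, .data$predicted)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
      ggplot2::labs(title = paste("True vs predicted -", best_name)),
    joint = ggplot2::ggplot(data, ggplot2::aes(.data$true, .data$predicted)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_abline(linetype = "dotted") +
      ggplot2::labs(title = paste("Joint plot (y = x dotted) -", best_name)),
    shap_bar = ggplot2::ggplot(
      data,
      ggplot2::aes(
        x = .data$mean_abs_attribution,
        y = stats::reorder(.data$feature, .data$mean_abs_attribution)
      )
    ) +
      ggplot2::geom_col(fill = "firebrick", alpha = 0.8) +
      ggplot2::labs(
        x = "mean |attribution|", y = NULL,
        title = paste("Global attribution ranking -", best_name)
      ),
    shap_dot = ggplot2::ggplot(
      data,
      ggplot2::aes(.data$attribution, .data$feature, colour = .data$value)
    ) +
      ggplot2::geom_jitter(height = 0.15, width = 0, alpha = 0.7) +
      ggplot2::scale_colour_gradient(low = "blue", high = "red") +
      ggplot2::facet_wrap(~class) +
      ggplot2::labs(
        x = "attribution", y = NULL,
        title = paste("Attribution dot plot -", best_name)
      ),
    permutation_bar = ggplot2::ggplot(
      utils::head(data, 20),
      ggplot2::aes(
        x = .data$importance,
        y = stats::reorder(.data$feature, .data$importance)
      )
    ) +
      ggplot2::geom_col(fill = "darkorange", alpha = 0.8) +
      ggplot2::labs(
        x = "permutation importance", y = NULL,
        title = paste("Permutation importance -", best_name)
      )
  )
}

#' Render requested plots from a run bundle
#'
#' One PNG and one companion CSV per plot, deterministic file names
#' (`<name>.png`, `<name>.csv`). Requesting a classification-only plot for a
#' regression run (or vice versa) is a validation error; an empty list is a
#' no-op.
#'
#' @param run An `oml_run`.
#' @param plot_names Character vector of plot names (may be empty).
#' @param out_dir Output directory.
#' @return Invisibly, the image paths written.
#' @export
render_plots <- function(run, plot_names, out_dir) {
  if (!length(plot_names)) {
    return(invisible(character()))
  }
  cls <- run$config$problem_type == "classification"
  bad <- if (cls) intersect(plot_names, REGRESSION_PLOTS) else intersect(plot_names, CLASSIFICATION_PLOTS)
  if (length(bad)) {
    stop(
      "plot(s) ", paste(bad, collapse = ", "), " are not valid for a ",
      run$config$problem_type, " run",
      call. = FALSE
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (name in plot_names) {
    data <- plot_data(run, name)
    readr::write_csv(data, file.path(out_dir, paste0(name, ".csv")))
    fig <- plot_figure(run, name, data)
    img <- file.path(out_dir, paste0(name, ".png"))
    ggplot2::ggsave(img, fig, width = 7, height = 5, dpi = 120)
    paths <- c(paths, img)
  }
  invisible(paths)
}

#' Plot a feature-selection accuracy curve
#'
#' @param object An `oml_selection_curve` (from [auto_select_k()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oml_selection_curve
#' @export
autoplot.oml_selection_curve <- function(object, ...) {
  chosen <- attr(object, "chosen_k")
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$k, .data$score)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = chosen, linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "number of selected features (log scale)",
      y = paste("CV", attr(object, "scoring")),
      title = paste0("Feature-selection curve (chosen k = ", chosen, ")")
    )
}

#' Plot the train/test performance plane used for model recommendation
#'
#' @param object An `oml_run`.
#' @param ... Unused.
#' @return A ggplot of train vs test scoring-metric values, the diagonal,
#'   and the recommended model highlighted.
#' @method autoplot oml_run
#' @export
autoplot.oml_run <- function(object, ...) {
  d <- object$best$distances |>
    dplyr::mutate(best = .data$model == object$best$winner)
  ggplot2::ggplot(d, ggplot2::aes(.data$train, .data$test, colour = .data$best)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::geom_text(ggplot2::aes(label = .data$model), vjust = -0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40")) +
    ggplot2::labs(
      x = paste("train", object$config$scoring),
      y = paste("test", object$config$scoring),
      title = "Model recommendation plane"
    )
}
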