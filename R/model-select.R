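#' Recommend the best model from the train/test performance plane
#'
#' Each tuned model is a point (train value, test value) of the configured
#' scoring metric. The recommended model is the one closest both to the ideal
#' point -- the origin (0, 0) for error-type metrics, the unit point (1, 1)
#' for score-type metrics, whose values are bounded above by 1 -- and to the
#' diagonal y = x, where train and test performance agree (distance from the
#' diagonal is the overfitting penalty). The two closeness criteria are
#' combined additively with equal weight:
#'
#' `D = sqrt((t - i)^2 + (v - i)^2) + |t - v| / sqrt(2)`
#'
#' with `t` the train value, `v` the test value and `i` the ideal (0 or 1).
#' The combination rule is isolated here so alternates are one-line swaps.
#' Exact ties (within 1e-12) go to the first model in registry order and are
#' reported in a tie note.
#'
#' @param points A tibble/data.frame with columns `model`, `train`, `test`,
#'   in registry order.
#' @param orientation `"score"` (ideal 1) or `"error"` (ideal 0).
#' @return List: `winner` (model name), `distances` (tibble with `D`),
#'   `tie_note` (character or `NULL`).
#' @export
select_best <- function(points, orientation = c("score", "error")) {
  orientation <- match.arg(orientation)
  if (!nrow(points)) stop("no models to select from", call. = FALSE)
  ideal <- if (orientation == "score") 1 else 0
  D <- best_model_distance(points$train, points$test, ideal)
  best <- min(D)
  tied <- which(D <= best + 1e-12)
  winner <- tied[1] # first in registry order
  tie_note <- NULL
  if (length(tied) > 1) {
    tie_note <- paste0(
      "Tie between models ",
      paste(points$model[tied], collapse = ", "),
      " (distance-to-ideal ", format(best, digits = 10),
      "); '", points$model[winner], "' picked by registry order."
    )
  }
  list(
    winner = points$model[winner],
    distances = tibble::tibble(
      model = points$model, train = points$train,
      test = points$test, D = D
    ),
    tie_note = tie_note
  )
}

#' Distance of a performance point to the ideal corner and the diagonal
#'
#' @param train,test Metric values on the two partitions.
#' @param ideal 1 for score-type metrics, 0 for error-type.
#' @return Numeric vector of distances `D`.
#' @export
best_model_distance <- function(train, test, ideal) {
  sqrt((train - ideal)^2 + (test - ideal)^2) + abs(train - test) / sqrt(2)
}
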