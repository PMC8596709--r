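#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a balanced random forest: per-class out-of-bag metrics
#'
#' @param x A `wb_brf`.
#' @param ... Unused.
#' @return Tibble with one row per class: `class`, `n`, `TPR`, `TNR`,
#'   `wAcc`, `clErr`.
#' @export
tidy.wb_brf <- function(x, ...) {
  oob_report(x)$metrics
}

#' One-row model summary of a balanced random forest
#'
#' @param x A `wb_brf`.
#' @param ... Unused.
#' @return One-row tibble: trees, variables per split, feature and class
#'   counts, training size, out-of-bag error.
#' @export
glance.wb_brf <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    vars_per_split = x$vars_per_split,
    n_features = length(x$features),
    n_classes = nlevels(x$train_y),
    n_train = length(x$train_y),
    oob_error = x$oob_error
  )
}

#' Tidy a classification report: per-class metrics
#'
#' @param x A `wb_report`.
#' @param ... Unused.
#' @return Per-class metrics tibble.
#' @export
tidy.wb_report <- function(x, ...) {
  x$metrics
}

#' One-row summary of a classification report
#'
#' @param x A `wb_report`.
#' @param ... Unused.
#' @return One-row tibble: `accuracy`, `error`, `n`.
#' @export
glance.wb_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    error = 1 - x$accuracy,
    n = nrow(x$observations)
  )
}

#' Tidy an importance table to long form
#'
#' @param x A `wb_importance`.
#' @param ... Unused.
#' @return Long tibble: `feature`, `class` (`"overall"`, `"gini"` or a class
#'   name), `importance`.
#' @export
tidy.wb_importance <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x),
    -"feature",
    names_to = "class", values_to = "importance"
  ) |>
    dplyr::mutate(class = sub("^mda_", "", .data$class))
}

#' Tidy a leave-one-species-out result: allocation proportions
#'
#' @param x A `wb_loso`.
#' @param ... Unused.
#' @return Tibble: `excluded`, `class`, `proportion`.
#' @export
tidy.wb_loso <- function(x, ...) {
  dplyr::mutate(x$allocation, excluded = x$excluded, .before = 1)
}
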