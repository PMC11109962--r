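# broom-style accessors for the fitted forest.

#' Tidy a responsiveness forest
#'
#' One row per feature with its mean-decrease-in-Gini importance.
#'
#' @param x A `responsiveness_forest` from [train_and_select()].
#' @param ... Unused.
#' @return Tibble `feature`, `importance`.
#' @export
tidy.responsiveness_forest <- function(x, ...) {
  imp <- randomForest::importance(x$fit)
  tibble(feature = rownames(imp),
         importance = unname(imp[, "MeanDecreaseGini"])) |>
    arrange(dplyr::desc(.data$importance))
}

#' Glance at a responsiveness forest
#'
#' @param x A `responsiveness_forest`.
#' @param ... Unused.
#' @return One-row tibble: selection outcome and validation metrics.
#' @export
glance.responsiveness_forest <- function(x, ...) {
  dplyr::bind_cols(
    tibble(seed = x$seed, n_trees = x$n_trees, qualified = x$qualified,
           selection_tpr = x$selection_tpr),
    x$validation_metrics
  )
}

#' @export
print.responsiveness_forest <- function(x, ...) {
  cat("Responsiveness random forest\n")
  cat(sprintf("  trees: %d, candidate seed: %d, qualified: %s\n",
              x$n_trees, x$seed, x$qualified))
  m <- x$validation_metrics
  cat(sprintf(
    "  validation: accuracy %.3f, dynamic TPR %.3f, static TPR %.3f, AUC %.3f\n",
    m$accuracy, m$tpr_dynamic, m$tpr_static, m$auc))
  invisible(x)
}
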