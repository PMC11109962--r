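# The five-feature responsiveness predictor: normalized peak significance,
# positional category (intron/exon collapsed to gene_body), SP1 flag,
# canonical RBPJ flag, degenerate RBPJ flag. Stratified 85/15 test split,
# then 80/20 train/validation; candidate forests are screened by the
# dynamic-class true-positive rate (> 65%) on validation (and, when given,
# an external labeled set, averaging the two).

FEATURE_COLS <- c("norm_p", "category", "has_sp1", "has_rbpj_canonical",
                  "has_rbpj_degenerate")

#' Assemble the five-feature table
#'
#' Joins consensus significance, positional annotation and motif flags
#' (plus binding-dynamics labels when supplied) into one row per site.
#' All inputs must be keyed by the identical `site_id` set.
#'
#' @param consensus Tibble from [build_consensus()] (`site_id`,
#'   `norm_score`).
#' @param annotations Tibble from [annotate_sites()] (`site_id`,
#'   `category`).
#' @param flags Tibble from [flag_sites()].
#' @param labels Optional tibble from [classify_sites()] (`site_id`,
#'   `label`); omit for a prediction-only table.
#' @return Tibble `site_id`, `norm_p`, `category`, `has_sp1`,
#'   `has_rbpj_canonical`, `has_rbpj_degenerate` and, when labels are
#'   given, `label`.
#' @export
build_feature_table <- function(consensus, annotations, flags,
                                labels = NULL) {
  check_ids <- function(x, nm) {
    if (anyDuplicated(x$site_id)) {
      abort(paste0("duplicated site_id in ", nm, ": ",
                   x$site_id[duplicated(x$site_id)][1]))
    }
    bad <- c(setdiff(x$site_id, consensus$site_id),
             setdiff(consensus$site_id, x$site_id))
    if (length(bad) > 0) {
      abort(paste0("site_id mismatch between consensus and ", nm, ": ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  check_ids(consensus, "consensus")
  check_ids(annotations, "annotations")
  check_ids(flags, "flags")
  out <- tibble(site_id = consensus$site_id,
                norm_p = consensus$norm_score) |>
    left_join(select(annotations, "site_id", "category"), by = "site_id") |>
    left_join(select(flags, "site_id", "has_sp1", "has_rbpj_canonical",
                     "has_rbpj_degenerate"), by = "site_id")
  out$category <- factor(as.character(out$category), levels = CATEGORY_LEVELS)
  if (!is.null(labels)) {
    check_ids(labels, "labels")
    out <- left_join(out, select(labels, "site_id", "label"), by = "site_id")
    out$label <- factor(as.character(out$label), levels = LABEL_LEVELS)
  }
  out
}

#' Stratified 85/15 + 80/20 data split
#'
#' First holds out `test_fraction` of the rows as the final test set; the
#' remaining model set is split into training and validation
#' (`validation_fraction` of the model set). Both splits are stratified by
#' label and fully determined by `seed`.
#'
#' @param table Labeled feature table (>= 20 rows, both labels present).
#' @param test_fraction Fraction held out for testing (default 0.15).
#' @param validation_fraction Fraction of the model set used for
#'   validation (default 0.20).
#' @param seed Integer seed.
#' @return Named list of tibbles `train`, `validation`, `test`.
#' @export
split_data <- function(table, test_fraction = 0.15,
                       validation_fraction = 0.20, seed = 1L) {
  if (!"label" %in% names(table) || anyNA(table$label)) {
    abort("split_data needs a fully labeled table")
  }
  if (nrow(table) < 20) abort("need at least 20 labeled rows")
  if (dplyr::n_distinct(table$label) < 2) {
    abort("both labels must be present")
  }
  if (test_fraction <= 0 || test_fraction >= 1 ||
      validation_fraction <= 0 || validation_fraction >= 1) {
    abort("fractions must lie in (0, 1)")
  }
  assign_split <- withr::with_seed(seed, {
    out <- rep(NA_character_, nrow(table))
    for (lv in levels(droplevels(table$label))) {
      idx <- sample(which(table$label == lv))
      n <- length(idx)
      n_test <- round(test_fraction * n)
      n_val <- round(validation_fraction * (n - n_test))
      out[idx[seq_len(n_test)]] <- "test"
      out[idx[n_test + seq_len(n_val)]] <- "validation"
      out[idx[(n_test + n_val + 1):n]] <- "train"
    }
    out
  })
  list(train = table[assign_split == "train", , drop = FALSE],
       validation = table[assign_split == "validation", , drop = FALSE],
       test = table[assign_split == "test", , drop = FALSE])
}

#' Model frame for the forest (factors with fixed levels)
#' @noRd
feature_frame <- function(table) {
  missing_cols <- setdiff(FEATURE_COLS, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data.frame(
    norm_p = as.numeric(table$norm_p),
    category = factor(as.character(table$category), levels = CATEGORY_LEVELS),
    has_sp1 = factor(table$has_sp1, levels = c(FALSE, TRUE)),
    has_rbpj_canonical = factor(table$has_rbpj_canonical,
                                levels = c(FALSE, TRUE)),
    has_rbpj_degenerate = factor(table$has_rbpj_degenerate,
                                 levels = c(FALSE, TRUE))
  )
}

#' @noRd
dynamic_tpr <- function(pred_label, truth_label) {
  pos <- truth_label == "dynamic"
  if (!any(pos)) return(NA_real_)
  mean(pred_label[pos] == "dynamic")
}

#' Train candidate forests and select by dynamic-class TPR
#'
#' Trains `n_candidates` random forests with seeds `seed_base`,
#' `seed_base + 1`, ... and returns the first whose mean dynamic-class
#' true-positive rate -- over the validation set and, when given, the
#' external labeled set -- exceeds `tpr_threshold`. If no candidate
#' qualifies, the best-scoring model is returned with `qualified = FALSE`.
#'
#' Class imbalance is handled with per-class weights inversely
#' proportional to class frequency (disable with `class_weights = FALSE`).
#'
#' @param train,validation Labeled feature tables from [split_data()].
#' @param external Optional external labeled feature table used alongside
#'   validation in the selection rule.
#' @param n_candidates Number of candidate seeds to try (default 25).
#' @param tpr_threshold Dynamic-class TPR bound for selection
#'   (default 0.65).
#' @param seed_base First candidate seed (default 1).
#' @param n_trees Trees per forest (default 500).
#' @param class_weights Weight classes inversely to frequency
#'   (default TRUE).
#' @return A `responsiveness_forest` object; see [tidy()] and [glance()]
#'   methods, [predict.responsiveness_forest()] and
#'   [evaluate_predictions()].
#' @export
train_and_select <- function(train, validation, external = NULL,
                             n_candidates = 25L, tpr_threshold = 0.65,
                             seed_base = 1L, n_trees = 500L,
                             class_weights = TRUE) {
  if (nrow(train) == 0) abort("empty training set")
  x <- feature_frame(train)
  y <- factor(as.character(train$label), levels = LABEL_LEVELS)
  if (anyNA(y)) abort("training labels missing")
  rf_args <- list(ntree = n_trees)
  if (class_weights) {
    # balanced per-tree bootstrap: each tree draws equally many cases per
    # class, i.e. cases weighted inversely to class frequency
    n_min <- min(table(y))
    rf_args$strata <- y
    rf_args$sampsize <- rep(n_min, nlevels(y))
  }
  best <- NULL
  for (k in seq_len(n_candidates)) {
    seed_k <- as.integer(seed_base + k - 1)
    fit <- withr::with_seed(seed_k, do.call(
      randomForest::randomForest,
      c(list(x = x, y = y), rf_args)))
    val_pred <- forest_predict(fit, validation)
    val_tpr <- dynamic_tpr(val_pred$label, validation$label)
    score <- val_tpr
    if (!is.null(external)) {
      ext_pred <- forest_predict(fit, external)
      score <- mean(c(val_tpr, dynamic_tpr(ext_pred$label, external$label)))
    }
    qualified <- !is.na(score) && score > tpr_threshold
    cand <- list(fit = fit, seed = seed_k, score = score,
                 qualified = qualified, val_pred = val_pred)
    if (is.null(best) || (!best$qualified && !is.na(score) &&
                          (is.na(best$score) || score > best$score))) {
      best <- cand
    }
    if (qualified) {
      best <- cand
      break
    }
  }
  metrics <- evaluate_predictions(
    mutate(best$val_pred, site_id = validation$site_id),
    select(validation, "site_id", "label"))
  structure(list(
    fit = best$fit,
    seed = best$seed,
    n_trees = n_trees,
    qualified = best$qualified,
    selection_tpr = best$score,
    tpr_threshold = tpr_threshold,
    validation_metrics = metrics,
    validation_predictions = mutate(best$val_pred,
                                    site_id = validation$site_id,
                                    truth = validation$label)
  ), class = "responsiveness_forest")
}

#' @noRd
forest_predict <- function(fit, table) {
  prob <- predict(fit, feature_frame(table), type = "prob")[, "dynamic"]
  tibble(p_dynamic = unname(prob),
         label = factor(if_else(prob >= 0.5, "dynamic", "static"),
                        levels = LABEL_LEVELS))
}

#' Predict responsiveness for new sites
#'
#' @param object A `responsiveness_forest` from [train_and_select()].
#' @param table Feature table with the training schema (label optional).
#' @param ... Unused.
#' @return Tibble `site_id`, `p_dynamic` (forest vote fraction for the
#'   dynamic class), `label` (`dynamic` iff `p_dynamic >= 0.5`).
#' @export
predict.responsiveness_forest <- function(object, table, ...) {
  out <- forest_predict(object$fit, table)
  mutate(out, site_id = table$site_id, .before = 1)
}

#' Accuracy, per-class TPR and AUC of predictions
#'
#' Accuracy is correct predictions over all predictions; per-class TPR is
#' correct-in-class over class size; AUC is the rank (Mann-Whitney)
#' statistic of the dynamic-class probabilities with ties sharing average
#' ranks.
#'
#' @param predictions Tibble `site_id`, `p_dynamic`, `label`
#'   (from [predict.responsiveness_forest()]).
#' @param truth Tibble `site_id`, `label`.
#' @return One-row tibble `n`, `accuracy`, `tpr_dynamic`, `tpr_static`,
#'   `auc`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (nrow(predictions) == 0) abort("empty predictions")
  m <- inner_join(predictions, rename(truth, truth = "label"),
                  by = "site_id")
  if (nrow(m) != nrow(predictions)) {
    abort("site_id mismatch between predictions and truth")
  }
  pos <- m$truth == "dynamic"
  auc <- if (any(pos) && any(!pos)) {
    r <- rank(m$p_dynamic)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  } else NA_real_
  tibble(
    n = nrow(m),
    accuracy = mean(m$label == m$truth),
    tpr_dynamic = if (any(pos)) mean(m$label[pos] == "dynamic") else NA_real_,
    tpr_static = if (any(!pos)) mean(m$label[!pos] == "static") else NA_real_,
    auc = auc
  )
}

#' Misclassified sites by positional category
#'
#' Tabulates falsely predicted static and falsely predicted dynamic sites
#' by category -- the check that the forest is not merely separating
#' promoter-proximal from distal sites.
#'
#' @param predictions Tibble from [predict.responsiveness_forest()].
#' @param truth Tibble `site_id`, `label`.
#' @param annotations Tibble from [annotate_sites()].
#' @return Tibble `error_type` (`false_static` / `false_dynamic`),
#'   `category`, `n`.
#' @export
misclassification_report <- function(predictions, truth, annotations) {
  m <- inner_join(predictions, rename(truth, truth = "label"),
                  by = "site_id") |>
    inner_join(select(annotations, "site_id", "category"), by = "site_id") |>
    filter(.data$label != .data$truth) |>
    mutate(error_type = if_else(.data$truth == "dynamic",
                                "false_static", "false_dynamic"))
  count(m, .data$error_type, .data$category, name = "n")
}
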