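test_that("the feature table assembles the five features and collapses gene bodies", {
  consensus <- tibble::tibble(site_id = c("s1", "s2"), norm_score = c(0.9, 0.1))
  ann <- tibble::tibble(site_id = c("s1", "s2"),
                        category = c("gene_body", "promoter"))
  flags <- tibble::tibble(site_id = c("s1", "s2"), has_sp1 = c(FALSE, TRUE),
                          has_rbpj_canonical = c(TRUE, FALSE),
                          has_rbpj_degenerate = c(TRUE, FALSE))
  ft <- build_feature_table(consensus, ann, flags)
  expect_equal(ft$norm_p, c(0.9, 0.1))
  expect_equal(as.character(ft$category), c("gene_body", "promoter"))
  expect_false("label" %in% names(ft))
  labels <- tibble::tibble(site_id = c("s1", "s2"),
                           label = c("dynamic", "static"))
  ft2 <- build_feature_table(consensus, ann, flags, labels)
  expect_equal(as.character(ft2$label), c("dynamic", "static"))
  # key integrity
  expect_error(build_feature_table(consensus, ann[1, ], flags), "mismatch")
  dup <- dplyr::bind_rows(ann, ann[1, ])
  expect_error(build_feature_table(consensus, dup, flags), "duplicated")
})

test_that("split_data gives stratified 68/17/15 partitions, deterministic in the seed", {
  ft <- toy_feature_table(n = 1000)
  sp <- split_data(ft, seed = 9)
  expect_equal(nrow(sp$test), 150, tolerance = 0)
  expect_true(abs(nrow(sp$validation) - 170) <= 1)
  expect_true(abs(nrow(sp$train) - 680) <= 1)
  # disjoint and exhaustive
  ids <- c(sp$train$site_id, sp$validation$site_id, sp$test$site_id)
  expect_equal(sort(ids), sort(ft$site_id))
  expect_equal(anyDuplicated(ids), 0L)
  # stratification: class fractions preserved within each partition
  frac <- mean(ft$label == "dynamic")
  for (part in sp) {
    expect_equal(mean(part$label == "dynamic"), frac, tolerance = 0.02)
  }
  # determinism
  sp2 <- split_data(ft, seed = 9)
  expect_identical(sp$train$site_id, sp2$train$site_id)
  sp3 <- split_data(ft, seed = 10)
  expect_false(identical(sp$train$site_id, sp3$train$site_id))
  # degenerate inputs
  expect_error(split_data(ft[1:10, ], seed = 1), "20")
  one_class <- dplyr::mutate(ft, label = factor("static",
                                                levels = c("dynamic", "static")))
  expect_error(split_data(one_class, seed = 1), "both labels")
})

test_that("a separable synthetic table trains a qualifying forest with perfect validation accuracy", {
  ft <- toy_feature_table(n = 600, seed = 77) |>
    dplyr::mutate(norm_p = ifelse(label == "dynamic", 0.9, 0.1))
  sp <- split_data(ft, seed = 5)
  fit <- train_and_select(sp$train, sp$validation, n_candidates = 3,
                          seed_base = 50)
  expect_s3_class(fit, "responsiveness_forest")
  expect_true(fit$qualified)
  expect_equal(fit$seed, 50L)
  expect_equal(fit$validation_metrics$accuracy, 1)
  expect_equal(fit$validation_metrics$tpr_dynamic, 1)
  # a duplicate of a training row predicts its training label
  pr <- predict(fit, sp$train[1:5, ])
  expect_equal(as.character(pr$label), as.character(sp$train$label[1:5]))
  expect_equal(nrow(pr), 5)
  expect_true(all(pr$p_dynamic >= 0 & pr$p_dynamic <= 1))
})

test_that("permuted labels never qualify and give chance-level AUC", {
  ft <- toy_feature_table(n = 600, seed = 78)
  perm <- withr::with_seed(99, dplyr::mutate(ft, label = sample(label)))
  sp <- split_data(perm, seed = 6)
  fit <- train_and_select(sp$train, sp$validation, n_candidates = 3,
                          seed_base = 60)
  expect_false(fit$qualified)
  expect_lt(fit$validation_metrics$auc, 0.65)
  expect_gt(fit$validation_metrics$auc, 0.35)
})

test_that("prediction validates the schema and probabilities are complementary", {
  ft <- toy_feature_table(n = 200, seed = 79)
  sp <- split_data(ft, seed = 2)
  fit <- train_and_select(sp$train, sp$validation, n_candidates = 1,
                          seed_base = 70)
  expect_error(predict(fit, dplyr::select(sp$test, -norm_p)), "norm_p")
  pr <- predict(fit, sp$test)
  full <- stats::predict(fit$fit, notchdyn:::feature_frame(sp$test),
                         type = "prob")
  expect_equal(unname(rowSums(full)), rep(1, nrow(sp$test)))
  expect_equal(pr$p_dynamic, unname(full[, "dynamic"]))
})

test_that("evaluation metrics match hand-counted values and the pair-counting oracle", {
  pred <- tibble::tibble(site_id = sprintf("s%d", 1:10),
                         p_dynamic = seq(0.95, 0.05, length.out = 10))
  pred$label <- factor(ifelse(pred$p_dynamic >= 0.5, "dynamic", "static"),
                       levels = c("dynamic", "static"))
  truth <- tibble::tibble(
    site_id = pred$site_id,
    label = factor(c("dynamic", "dynamic", "static", "dynamic", "dynamic",
                     "static", "dynamic", "static", "static", "static"),
                   levels = c("dynamic", "static")))
  ev <- evaluate_predictions(pred, truth)
  expect_equal(ev$accuracy, 0.8)  # 8 of 10 correct
  expect_equal(ev$tpr_dynamic, 4 / 5)
  expect_equal(ev$tpr_static, 4 / 5)
  # AUC from the stated example: scores (.9,.8,.4,.2), labels (1,0,1,0)
  p4 <- tibble::tibble(site_id = paste0("x", 1:4),
                       p_dynamic = c(0.9, 0.8, 0.4, 0.2))
  p4$label <- factor("static", levels = c("dynamic", "static"))
  t4 <- tibble::tibble(site_id = p4$site_id,
                       label = factor(c("dynamic", "static", "dynamic",
                                        "static"),
                                      levels = c("dynamic", "static")))
  expect_equal(evaluate_predictions(p4, t4)$auc, 0.75)
  # random scores against the exhaustive pair-counting oracle
  withr::with_seed(41, {
    sc <- round(runif(30), 2)  # ties included
    lb <- rbinom(30, 1, 0.4)
    pr <- tibble::tibble(site_id = paste0("r", 1:30), p_dynamic = sc)
    pr$label <- factor("static", levels = c("dynamic", "static"))
    tr <- tibble::tibble(site_id = pr$site_id,
                         label = factor(ifelse(lb == 1, "dynamic", "static"),
                                        levels = c("dynamic", "static")))
    expect_equal(evaluate_predictions(pr, tr)$auc, oracle_auc(sc, lb))
  })
  # perfect ranking
  expect_equal(evaluate_predictions(pred, dplyr::mutate(
    truth, label = pred$label))$auc, 1)
  expect_error(evaluate_predictions(pred[0, ], truth), "empty")
})

test_that("training and selection are deterministic in their seeds", {
  ft <- toy_feature_table(n = 300, seed = 80)
  sp <- split_data(ft, seed = 3)
  f1 <- train_and_select(sp$train, sp$validation, n_candidates = 2,
                         seed_base = 90)
  f2 <- train_and_select(sp$train, sp$validation, n_candidates = 2,
                         seed_base = 90)
  expect_identical(glance(f1), glance(f2))
  expect_identical(predict(f1, sp$test), predict(f2, sp$test))
})

test_that("removing motif and strength features lowers validation AUC on planted signal", {
  aucs <- sapply(1:6, function(s) {
    ft <- toy_feature_table(n = 700, seed = 200 + s)
    sp <- split_data(ft, seed = s)
    full <- train_and_select(sp$train, sp$validation, n_candidates = 1,
                             seed_base = s, n_trees = 200)
    # ablation: wipe motif flags and strength, keep only category
    wipe <- function(t) dplyr::mutate(t, norm_p = 0.5, has_sp1 = FALSE,
                                      has_rbpj_canonical = FALSE,
                                      has_rbpj_degenerate = FALSE)
    abl <- train_and_select(wipe(sp$train), wipe(sp$validation),
                            n_candidates = 1, seed_base = s, n_trees = 200)
    c(full$validation_metrics$auc, abl$validation_metrics$auc)
  })
  expect_gt(mean(aucs[1, ]), mean(aucs[2, ]))
})

test_that("tidy/glance expose importance and metrics in broom shape", {
  ft <- toy_feature_table(n = 200, seed = 81)
  sp <- split_data(ft, seed = 4)
  fit <- train_and_select(sp$train, sp$validation, n_candidates = 1,
                          seed_base = 30, n_trees = 100)
  td <- tidy(fit)
  expect_setequal(td$feature, notchdyn:::FEATURE_COLS)
  expect_true(all(td$importance >= 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("accuracy", "tpr_dynamic", "auc", "qualified") %in%
                    names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
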