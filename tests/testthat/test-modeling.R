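test_that("stratified folds cover every row once with balanced classes", {
  set.seed(1)
  y <- rbinom(97, 1, 0.3)
  folds <- stratified_folds(y, k = 10, seed = 5)
  expect_length(folds, 97)
  expect_setequal(unique(folds), 1:10)
  pos_per_fold <- tabulate(folds[y == 1], 10)
  neg_per_fold <- tabulate(folds[y == 0], 10)
  expect_lte(diff(range(pos_per_fold)), 1)
  expect_lte(diff(range(neg_per_fold)), 1)
  expect_identical(folds, stratified_folds(y, k = 10, seed = 5))
  expect_false(identical(folds, stratified_folds(y, k = 10, seed = 6)))
})

test_that("cross-validation scores every row exactly once out of fold", {
  tab <- separable_table(n = 60, seed = 2)
  cv <- cv_config(k_folds = 5, seed = 3)
  res <- fit_predict_cv(model_spec("logreg_l2", list(lambda = 0.01)), tab, cv)
  expect_false(anyNA(res$oof_scores))
  expect_length(res$oof_scores, nrow(tab))
  expect_length(res$fold_auc, 5L)
})

test_that("every model family separates an almost-deterministic signal", {
  tab <- separable_table(n = 80, seed = 4)
  cv <- cv_config(k_folds = 5, seed = 1)
  for (kind in c("logreg_l1", "logreg_l2", "svm", "gbt")) {
    params <- switch(kind,
                     logreg_l1 = list(lambda = 0.01),
                     logreg_l2 = list(lambda = 0.01),
                     svm = list(cost = 1, kernel = "linear"),
                     gbt = list(nrounds = 50, max_depth = 2, eta = 0.3))
    res <- fit_predict_cv(model_spec(kind, params), tab, cv)
    expect_gte(res$mean_auc, 0.97)
  }
})

test_that("permuted labels give chance-level cross-validated AUC", {
  set.seed(9)
  n <- 500
  dt <- data.table::data.table(user_id = sprintf("u%03d", 1:n),
                               f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
                               y = sample(rep(0:1, each = n / 2)))
  data.table::setattr(dt, "class", c("user_table", "data.table", "data.frame"))
  res <- fit_predict_cv(model_spec("logreg_l2", list(lambda = 0.1)), dt,
                        cv_config(k_folds = 10, seed = 2))
  expect_gt(res$mean_auc, 0.40)
  expect_lt(res$mean_auc, 0.60)
})

test_that("a single-class fold yields a missing fold AUC with a warning", {
  # 2 positives across 3 stratified folds: one validation fold has none,
  # while every training split still sees both classes
  set.seed(4)
  dt <- data.table::data.table(user_id = sprintf("u%02d", 1:30),
                               x = rnorm(30),
                               y = c(rep(0L, 28), 1L, 1L))
  data.table::setattr(dt, "class", c("user_table", "data.table", "data.frame"))
  expect_warning(
    res <- fit_predict_cv(model_spec("gbt", list(nrounds = 10, max_depth = 2,
                                                 eta = 0.3)), dt,
                          cv_config(k_folds = 3, seed = 1)),
    "single class")
  expect_true(anyNA(res$fold_auc))
  expect_false(is.na(res$mean_auc))  # mean over the defined folds
})

test_that("grid search returns the argmax and breaks ties by grid order", {
  tab <- separable_table(n = 60, seed = 6)
  cv <- cv_config(k_folds = 5, seed = 2)
  single <- list(list(lambda = 0.05))
  gs <- grid_search("logreg_l2", single, tab, cv)
  expect_equal(gs$best_params, single[[1]])

  # a degenerate setting (shrinkage zeroing every coefficient) loses to a
  # sane one on separable data
  gs2 <- grid_search("logreg_l1",
                     list(list(lambda = 1e6), list(lambda = 0.01)), tab, cv)
  expect_equal(gs2$best_params$lambda, 0.01)

  # identical duplicated entries: the first is returned
  gs3 <- grid_search("gbt",
                     list(list(nrounds = 20, max_depth = 2, eta = 0.3),
                          list(nrounds = 20, max_depth = 2, eta = 0.3)),
                     tab, cv)
  expect_equal(gs3$results$mean_auc[1], gs3$results$mean_auc[2])
  expect_equal(gs3$best_auc, gs3$results$mean_auc[1])
})

test_that("fixed seeds make fold assignment and deterministic learners reproducible", {
  tab <- separable_table(n = 60, seed = 8)
  cv <- cv_config(k_folds = 5, seed = 7)
  for (kind in c("logreg_l2", "gbt")) {
    params <- if (kind == "gbt") list(nrounds = 30, max_depth = 2, eta = 0.3)
              else list(lambda = 0.05)
    r1 <- fit_predict_cv(model_spec(kind, params), tab, cv)
    r2 <- fit_predict_cv(model_spec(kind, params), tab, cv)
    expect_identical(r1$oof_scores, r2$oof_scores)
    expect_identical(r1$fold_auc, r2$fold_auc)
  }
})

test_that("categorical features are one-hot encoded without leaking test levels", {
  set.seed(12)
  n <- 40
  dt <- data.table::data.table(
    user_id = sprintf("u%02d", 1:n),
    grp = sample(c("a", "b", "c"), n, replace = TRUE),
    x = rnorm(n),
    y = rbinom(n, 1, 0.5))
  data.table::setattr(dt, "class", c("user_table", "data.table", "data.frame"))
  res <- fit_predict_cv(model_spec("logreg_l2", list(lambda = 0.1)), dt,
                        cv_config(k_folds = 4, seed = 1))
  expect_false(anyNA(res$oof_scores))
})
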