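fast_train <- function(...) {
  do.call(train_config,
          utils::modifyList(list(epochs = 2, folds = 2, seeds = 1L),
                            list(...)))
}

test_that("k-fold report bookkeeping and self-consistency hold", {
  co <- small_cohort(seed = 21)
  rep <- run_kfold_experiment(co, model = "logistic_regression",
                              selector = selector_config(top_n = 5),
                              train = fast_train(folds = 3, seeds = 1:2))
  expect_s3_class(rep, "vt_eval_report")
  expect_equal(nrow(rep$metrics), 3 * 2)  # k folds x |seeds| rows
  expect_true(all(rep$metrics$auc >= 0 & rep$metrics$auc <= 1))
  expect_true(all(rep$summary$sd >= 0))
  # summary mean recomputable from the per-fold entries
  expect_equal(rep$summary$mean[rep$summary$metric == "auc"],
               mean(rep$metrics$auc))
  per_seed <- tapply(rep$metrics$auc, rep$metrics$seed, mean)
  expect_equal(rep$summary$sd[rep$summary$metric == "auc"],
               sd(per_seed))
  # tidy/glance surface the same numbers
  expect_equal(tidy(rep), rep$metrics)
  g <- glance(rep)
  expect_equal(g$auc, mean(rep$metrics$auc))
  expect_equal(g$n_folds, 3)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("every classifier kind runs through the pipeline", {
  co <- small_cohort(seed = 22, effect_size = 2)
  kinds <- c("xgboost", "gradient_boosting", "adaboost", "random_forest",
             "decision_tree", "svm", "kneighbors", "logistic_regression",
             "gaussian_nb")
  for (kind in kinds) {
    rep <- suppressWarnings(run_kfold_experiment(
      co, model = kind, selector = selector_config(top_n = 4),
      train = fast_train()))
    expect_equal(nrow(rep$metrics), 2)
    expect_true(all(is.finite(rep$metrics$auc)), label = kind)
    # strong planted effect: every baseline beats chance
    expect_gt(mean(rep$metrics$auc), 0.6)
  }
  # the two neural models on tiny settings
  for (kind in c("vocaltab", "mlp")) {
    ma <- if (kind == "vocaltab") tiny_model_args() else list(hidden = c(32, 16))
    rep <- run_kfold_experiment(co, model = kind,
                                selector = selector_config(top_n = 4),
                                train = fast_train(epochs = 10),
                                model_args = ma)
    expect_gt(mean(rep$metrics$auc), 0.6)
  }
})

test_that("a null cohort gives chance-level AUC through the full pipeline", {
  co0 <- small_cohort(seed = 23, effect_size = 0, n_case_subjects = 16,
                      n_control_subjects = 12)
  rep <- suppressWarnings(run_kfold_experiment(
    co0, model = "gaussian_nb", selector = selector_config(top_n = 6),
    train = fast_train(folds = 4, seeds = 1:2)))
  expect_gt(mean(rep$metrics$auc), 0.25)
  expect_lt(mean(rep$metrics$auc), 0.75)
})

test_that("selection can be skipped and per-fold scopes work", {
  co <- small_cohort(seed = 24)
  rep_all <- run_kfold_experiment(co, model = "logistic_regression",
                                  selector = NULL, train = fast_train())
  expect_equal(nrow(rep_all$metrics), 2)
  rep_pf <- run_kfold_experiment(co, model = "decision_tree",
                                 selector = selector_config(top_n = 4),
                                 train = fast_train(),
                                 scaler_scope = "per_fold",
                                 select_scope = "per_fold")
  expect_equal(nrow(rep_pf$metrics), 2)
})

test_that("no test-fold row influences per-fold training", {
  co <- small_cohort(seed = 25, gender = FALSE)
  plan <- make_grouped_stratified_folds(co, k = 3, seed = 1)
  fr <- fold_rows(co, plan, 1)

  fit_fold <- function(data) {
    sdata <- apply_standardizer(data, fit_standardizer(data, rows = fr$train))
    rk <- rank_features_gbdt(sdata[fr$train, ], selector_config(seed = 1))
    feats <- select_top_n(rk, 4)
    bal <- balance_training_fold(sdata[c("subject_id", "label", feats)],
                                 plan, 1, k_neighbors = 3, seed = 2)
    train_model(bal$x, bal$y,
                do.call(vocaltab_config,
                        c(list(n_features = 4, seed = 3), tiny_model_args())),
                fast_train(), seed = 3)
  }
  fit1 <- fit_fold(co)
  # corrupt every test row's features; trained weights must not move
  co2 <- co
  fn <- feature_names(co)
  co2[fr$test, fn] <- co2[fr$test, fn] + 100
  fit2 <- fit_fold(co2)
  expect_identical(fit1$pars, fit2$pars)
})

test_that("sweeps cover their axes and respect head divisibility", {
  co <- small_cohort(seed = 26, effect_size = 2)
  tr <- fast_train(epochs = 2)
  sw <- run_sweep(co, axis = "n_heads", grid = c(1, 2, 4),
                  model = "vocaltab", selector = selector_config(top_n = 4),
                  train = tr, model_args = tiny_model_args(n_encoders = 1))
  expect_equal(sw$value, c(1, 2, 4))
  expect_true(all(is.finite(sw$mean_auc)))
  expect_s3_class(autoplot(sw), "ggplot")

  # more selected features never hurt much on a strong-effect cohort
  sw2 <- run_sweep(co, axis = "top_n", grid = c(2, 4, 8),
                   model = "logistic_regression",
                   selector = selector_config(top_n = 4),
                   train = fast_train(folds = 3))
  expect_gte(sw2$mean_auc[3], sw2$mean_auc[1] - 0.05)

  # batch-size axis reaches the trainer
  sw3 <- run_sweep(co, axis = "batch_size", grid = c(8, 32),
                   model = "mlp", selector = selector_config(top_n = 4),
                   train = tr, model_args = list(hidden = c(8, 4)))
  expect_equal(nrow(sw3), 2)
})
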