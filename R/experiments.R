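#' @importFrom rlang .data
NULL

MODEL_KINDS <- c("vocaltab", "mlp", "xgboost", "gradient_boosting",
                 "adaboost", "random_forest", "decision_tree", "svm",
                 "kneighbors", "logistic_regression", "gaussian_nb")

# fit one classifier kind on a training matrix; returns a predict closure
fit_classifier <- function(kind, x, y, seed, train = train_config(),
                           model_args = list()) {
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  yf <- factor(y, levels = c(0, 1))
  switch(
    kind,
    vocaltab = {
      cfg <- do.call(vocaltab_config,
                     utils::modifyList(list(n_features = ncol(x), seed = seed),
                                       model_args))
      fit <- train_model(x, y, cfg, train, seed = seed)
      function(newx) predict(fit, newx)
    },
    mlp = {
      cfg <- do.call(mlp_config,
                     utils::modifyList(list(n_features = ncol(x), seed = seed),
                                       model_args))
      fit <- train_mlp(x, y, cfg, train, seed = seed)
      function(newx) predict(fit, newx)
    },
    xgboost = {
      # tuned gbtree baseline settings
      fit <- withr::with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.2,
                      max_depth = 10, colsample_bytree = 0.3, gamma = 0,
                      min_child_weight = 1, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y), nrounds = 100,
        verbose = 0))
      function(newx) predict(fit, xgboost::xgb.DMatrix(newx))
    },
    gradient_boosting = {
      # classic gradient boosting: shallow trees, slow learning rate
      fit <- withr::with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1,
                      max_depth = 3, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y), nrounds = 100,
        verbose = 0))
      function(newx) predict(fit, xgboost::xgb.DMatrix(newx))
    },
    adaboost = fit_adaboost(x, y, seed = seed),
    random_forest = {
      fit <- withr::with_seed(seed, randomForest::randomForest(x, yf))
      function(newx) predict(fit, newx, type = "prob")[, "1"]
    },
    decision_tree = {
      df <- data.frame(x)
      df$.y <- yf
      fit <- withr::with_seed(seed, rpart::rpart(.y ~ ., df, method = "class"))
      function(newx) predict(fit, data.frame(newx), type = "prob")[, "1"]
    },
    svm = {
      fit <- withr::with_seed(seed,
                              e1071::svm(x, yf, probability = TRUE,
                                         scale = FALSE))
      function(newx) {
        pr <- predict(fit, newx, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      }
    },
    kneighbors = {
      function(newx) {
        withr::with_seed(seed, {
          pr <- class::knn(x, newx, yf, k = 5, prob = TRUE)
          p <- attr(pr, "prob")
          ifelse(pr == "1", p, 1 - p)
        })
      }
    },
    logistic_regression = {
      df <- data.frame(x)
      df$.y <- y
      fit <- suppressWarnings(stats::glm(.y ~ ., df, family = stats::binomial()))
      function(newx) {
        suppressWarnings(unname(predict(fit, data.frame(newx),
                                        type = "response")))
      }
    },
    gaussian_nb = {
      fit <- e1071::naiveBayes(x, yf)
      function(newx) predict(fit, newx, type = "raw")[, "1"]
    },
    stop("unknown model kind: ", kind, call. = FALSE)
  )
}

# AdaBoost (SAMME) with decision stumps; score = alpha-weighted vote share
fit_adaboost <- function(x, y, n_rounds = 50, seed = 1) {
  m <- nrow(x)
  df <- data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  w <- rep(1 / m, m)
  stumps <- list(); alphas <- numeric(0)
  withr::with_seed(seed, {
    for (t in seq_len(n_rounds)) {
      fit <- rpart::rpart(.y ~ ., df, weights = w, method = "class",
                          control = rpart::rpart.control(maxdepth = 1,
                                                         cp = -1,
                                                         minsplit = 2))
      pred <- predict(fit, df, type = "class")
      err <- sum(w[pred != df$.y]) / sum(w)
      if (err <= 0) {
        stumps[[t]] <- fit; alphas[t] <- 10
        break
      }
      if (err >= 0.5) break
      alpha <- log((1 - err) / err)
      stumps[[t]] <- fit; alphas[t] <- alpha
      w <- w * exp(alpha * (pred != df$.y))
      w <- w / sum(w)
    }
  })
  if (length(stumps) == 0L) {
    p0 <- mean(y)
    return(function(newx) rep(p0, nrow(newx)))
  }
  function(newx) {
    nd <- data.frame(newx)
    votes <- vapply(stumps, function(s) {
      as.numeric(predict(s, nd, type = "class") == "1")
    }, numeric(nrow(nd)))
    votes <- matrix(votes, nrow = nrow(nd))
    drop(votes %*% alphas) / sum(alphas)
  }
}

#' Run a subject-grouped k-fold experiment
#'
#' The full evaluation pipeline: standardize, rank + select features,
#' ADASYN-oversample the minority class of each training fold, train the
#' chosen classifier, and score the untouched test fold; repeated over
#' `train$seeds` with a fresh fold plan per seed, and aggregated as
#' mean +/- sd per metric.
#'
#' By default standardization and feature selection are fit on the
#' complete table (`scope = "global"`), reproducing the protocol of the
#' original study; `"per_fold"` refits both on each training fold only,
#' which is the leakage-safe variant. ADASYN and model training always
#' see only training rows.
#'
#' @param data A `dysphonia_tbl`.
#' @param model One of `"vocaltab"`, `"mlp"`, `"xgboost"`,
#'   `"gradient_boosting"`, `"adaboost"`, `"random_forest"`,
#'   `"decision_tree"`, `"svm"`, `"kneighbors"`,
#'   `"logistic_regression"`, `"gaussian_nb"`.
#' @param selector A `vt_selector_config`, or `NULL` to skip feature
#'   selection and use every feature.
#' @param train A `vt_train_config` (folds, seeds, and the network's
#'   optimizer settings).
#' @param model_args Named list of overrides for [vocaltab_config()] /
#'   [mlp_config()] (e.g. `embed_dim`, `n_encoders`, `hidden`).
#' @param scaler_scope,select_scope `"global"` or `"per_fold"`.
#' @param adasyn_k,adasyn_beta ADASYN neighbourhood size and balance
#'   ratio; `adasyn_beta = NULL` disables oversampling.
#' @return A `vt_eval_report`: list with `metrics` (tibble of seed, fold,
#'   auc, precision, recall), `summary` (mean +/- sd per metric),
#'   `features` (selected feature names, global mode), and provenance.
#' @export
run_kfold_experiment <- function(data, model = "vocaltab",
                                 selector = selector_config(),
                                 train = train_config(),
                                 model_args = list(),
                                 scaler_scope = c("global", "per_fold"),
                                 select_scope = c("global", "per_fold"),
                                 adasyn_k = 5, adasyn_beta = 1) {
  model <- match.arg(model, MODEL_KINDS)
  scaler_scope <- match.arg(scaler_scope)
  select_scope <- match.arg(select_scope)
  k <- train$folds
  # the trainable pipeline consumes continuous features only; gender (when
  # present) is examined by the rankers directly, not carried downstream
  data <- data[setdiff(names(data), "gender")]

  rows_list <- list()
  feats_global <- NULL
  for (s in train$seeds) {
    plan <- make_grouped_stratified_folds(data, k = k, seed = s)
    if (scaler_scope == "global") {
      sdata <- apply_standardizer(data, fit_standardizer(data))
    }
    if (select_scope == "global" && !is.null(selector)) {
      stopifnot(scaler_scope == "global")
      rk <- rank_features(sdata, selector)
      feats_global <- select_top_n(rk, selector$top_n)
    }
    for (f in seq_len(k)) {
      fold_seed <- (s * 100L + f) %% .Machine$integer.max
      fr <- fold_rows(data, plan, f)
      if (scaler_scope == "per_fold") {
        sdata <- apply_standardizer(data,
                                    fit_standardizer(data, rows = fr$train))
      }
      feats <- if (is.null(selector)) {
        feature_names(sdata)
      } else if (select_scope == "per_fold") {
        sel2 <- selector
        sel2$seed <- fold_seed
        rk <- rank_features(sdata[fr$train, , drop = FALSE], sel2)
        select_top_n(rk, selector$top_n)
      } else {
        feats_global
      }
      xmat <- as.matrix(sdata[feats])
      xtr <- xmat[fr$train, , drop = FALSE]
      ytr <- sdata$label[fr$train]
      if (!is.null(adasyn_beta)) {
        aug <- adasyn_oversample(xtr, ytr, k_neighbors = adasyn_k,
                                 balance_ratio = adasyn_beta,
                                 seed = fold_seed)
        xtr <- aug$x; ytr <- aug$y
      }
      clf <- fit_classifier(model, xtr, ytr, seed = fold_seed,
                            train = train, model_args = model_args)
      sc <- clf(xmat[fr$test, , drop = FALSE])
      yte <- sdata$label[fr$test]
      pr <- suppressWarnings(precision_recall(sc, yte, train$threshold))
      rows_list[[length(rows_list) + 1L]] <- tibble::tibble(
        seed = s, fold = f, auc = roc_auc(sc, yte),
        precision = pr[["precision"]], recall = pr[["recall"]])
    }
  }
  metrics <- dplyr::bind_rows(rows_list)
  new_eval_report(metrics, model = model, selector = selector,
                  train = train, model_args = model_args,
                  scaler_scope = scaler_scope, select_scope = select_scope,
                  features = feats_global)
}

new_eval_report <- function(metrics, ...) {
  per_seed <- metrics |>
    dplyr::group_by(.data$seed) |>
    dplyr::summarise(dplyr::across(c("auc", "precision", "recall"), mean),
                     .groups = "drop")
  n_seeds <- nrow(per_seed)
  summarise_metric <- function(metric) {
    mu <- mean(metrics[[metric]])
    sdv <- if (n_seeds > 1L) {
      stats::sd(per_seed[[metric]])
    } else {
      stats::sd(metrics[[metric]])
    }
    tibble::tibble(metric = metric, mean = mu, sd = sdv)
  }
  summary <- dplyr::bind_rows(lapply(c("auc", "precision", "recall"),
                                     summarise_metric))
  structure(list(metrics = metrics, per_seed = per_seed, summary = summary,
                 provenance = list(...)),
            class = "vt_eval_report")
}

#' @export
print.vt_eval_report <- function(x, ...) {
  p <- x$provenance
  cat("<vt_eval_report> model =", p$model,
      "| folds x seeds =", max(x$metrics$fold), "x",
      length(unique(x$metrics$seed)), "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Sweep one hyperparameter axis
#'
#' Repeats [run_kfold_experiment()] over a grid of values on one axis,
#' everything else held fixed:
#' \describe{
#'   \item{`batch_size`}{training minibatch size}
#'   \item{`n_heads`}{attention heads (transformer only)}
#'   \item{`top_n`}{number of selected features}
#'   \item{`depth`}{encoder-block count for the transformer; for the MLP
#'     baseline, the number of stacked hidden layers, each of width
#'     `model_args$depth_width` (default 1024)}
#' }
#'
#' @inheritParams run_kfold_experiment
#' @param axis One of `"batch_size"`, `"n_heads"`, `"top_n"`, `"depth"`.
#' @param grid Vector of axis values.
#' @return A `vt_sweep` tibble: `axis`, `value`, `mean_auc`, `sd_auc`,
#'   `mean_precision`, `mean_recall`; the full reports are in the
#'   `reports` attribute.
#' @export
run_sweep <- function(data, axis = c("batch_size", "n_heads", "top_n",
                                     "depth"),
                      grid, model = "vocaltab",
                      selector = selector_config(),
                      train = train_config(), model_args = list(),
                      scaler_scope = "global", select_scope = "global",
                      adasyn_k = 5, adasyn_beta = 1) {
  axis <- match.arg(axis)
  stopifnot(length(grid) >= 1)
  reports <- lapply(grid, function(v) {
    tr <- train; sel <- selector; ma <- model_args
    switch(axis,
           batch_size = { tr$batch_size <- v },
           n_heads = { ma$n_heads <- v },
           top_n = { sel$top_n <- v },
           depth = {
             if (model == "vocaltab") {
               ma$n_encoders <- v
             } else {
               width <- ma$depth_width %||% 1024L
               ma$hidden <- rep(width, v)
             }
           })
    ma$depth_width <- NULL
    run_kfold_experiment(data, model = model, selector = sel, train = tr,
                         model_args = ma, scaler_scope = scaler_scope,
                         select_scope = select_scope, adasyn_k = adasyn_k,
                         adasyn_beta = adasyn_beta)
  })
  out <- purrr::map2_dfr(grid, reports, function(v, r) {
    s <- r$summary
    tibble::tibble(axis = axis, value = v,
                   mean_auc = s$mean[s$metric == "auc"],
                   sd_auc = s$sd[s$metric == "auc"],
                   mean_precision = s$mean[s$metric == "precision"],
                   mean_recall = s$mean[s$metric == "recall"])
  })
  structure(out, class = c("vt_sweep", class(out)), reports = reports,
            model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
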