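#' Selector configuration
#'
#' @param method Ranking method: `"gbdt_gain"` (average split gain of a
#'   gradient-boosted tree ensemble), `"svc_weight"` (absolute weights of
#'   a linear support-vector classifier), or `"permutation"` (mean drop
#'   in held-in SVC accuracy when a feature column is shuffled).
#' @param top_n How many top-ranked features to keep (96 is the
#'   configuration used throughout for the 753-feature table).
#' @param n_estimators,learning_rate,max_depth Gradient-boosted tree
#'   parameters (gbtree booster).
#' @param cost Linear-SVC regularization constant C.
#' @param permutation_repeats Shuffles per feature for the permutation
#'   score.
#' @param seed Integer seed.
#' @return A `vt_selector_config` list.
#' @export
selector_config <- function(method = c("gbdt_gain", "svc_weight",
                                       "permutation"),
                            top_n = 96, n_estimators = 100,
                            learning_rate = 0.3, max_depth = 6,
                            cost = 1, permutation_repeats = 5, seed = 1) {
  method <- match.arg(method)
  stopifnot(top_n >= 1, n_estimators >= 1, permutation_repeats >= 1)
  structure(list(method = method, top_n = top_n,
                 n_estimators = n_estimators,
                 learning_rate = learning_rate, max_depth = max_depth,
                 cost = cost, permutation_repeats = permutation_repeats,
                 seed = seed),
            class = "vt_selector_config")
}

new_ranking <- function(feature, score, method) {
  stopifnot(length(feature) == length(score), all(score >= 0 | is.na(score)))
  col_index <- seq_along(feature)
  ord <- order(-score, col_index)
  out <- tibble::tibble(feature = feature[ord], score = score[ord],
                        col_index = col_index[ord],
                        rank = seq_along(feature))
  structure(out, class = c("vt_ranking", class(out)), method = method)
}

rank_input <- function(data, include_gender = TRUE) {
  x <- feature_matrix(data, include_gender = include_gender &&
                        "gender" %in% names(data))
  y <- data$label
  if (length(unique(y)) < 2L) {
    stop("need both classes to rank features", call. = FALSE)
  }
  list(x = x, y = y)
}

#' Rank features by gradient-boosted tree gain
#'
#' Trains a gbtree classifier on the full provided table and scores each
#' feature by the average loss-reduction ("gain") over all tree splits
#' that use it; features never used by a split score 0. Features are then
#' sorted by descending score (ties broken by original column index), and
#' the top N are what the downstream network trains on.
#'
#' @param data A `dysphonia_tbl`. A `gender` column, when present, is
#'   ranked alongside the continuous features (as a 0/1 indicator).
#' @param config A `vt_selector_config`.
#' @return A `vt_ranking` tibble: `feature`, `score`, `col_index`, `rank`.
#' @export
rank_features_gbdt <- function(data, config = selector_config()) {
  inp <- rank_input(data)
  dtrain <- xgboost::xgb.DMatrix(inp$x, label = inp$y)
  bst <- withr::with_seed(config$seed, {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", booster = "gbtree",
                    eta = config$learning_rate,
                    max_depth = config$max_depth, nthread = 1),
      data = dtrain, nrounds = config$n_estimators, verbose = 0)
  })
  tr <- xgboost::xgb.model.dt.tree(model = bst)
  tr <- tr[tr$Feature != "Leaf", c("Feature", "Gain")]
  avg_gain <- tapply(tr$Gain, tr$Feature, mean)
  score <- stats::setNames(rep(0, ncol(inp$x)), colnames(inp$x))
  score[names(avg_gain)] <- avg_gain
  new_ranking(colnames(inp$x), unname(score), "gbdt_gain")
}

#' Rank features by linear SVC weight magnitude
#'
#' Fits a linear support-vector classifier on the full table; importance
#' of feature j is the absolute value of its primal weight |w_j|.
#'
#' @inheritParams rank_features_gbdt
#' @return A `vt_ranking`.
#' @export
rank_features_svc <- function(data, config = selector_config(method = "svc_weight")) {
  inp <- rank_input(data)
  fit <- withr::with_seed(config$seed, {
    e1071::svm(inp$x, factor(inp$y), kernel = "linear", cost = config$cost,
               scale = FALSE)
  })
  w <- drop(t(fit$coefs) %*% fit$SV)
  new_ranking(colnames(inp$x), abs(w), "svc_weight")
}

#' Rank features by permutation importance
#'
#' Fits a linear SVC once, then scores each feature by the mean drop in
#' held-in accuracy when that column is shuffled, averaged over
#' `permutation_repeats` shuffles. Negative drops are floored at 0.
#'
#' @inheritParams rank_features_gbdt
#' @return A `vt_ranking`.
#' @export
rank_features_permutation <- function(data,
                                      config = selector_config(method = "permutation")) {
  inp <- rank_input(data)
  y <- factor(inp$y)
  fit <- withr::with_seed(config$seed, {
    e1071::svm(inp$x, y, kernel = "linear", cost = config$cost, scale = FALSE)
  })
  base_acc <- mean(stats::predict(fit, inp$x) == y)
  drops <- withr::with_seed(config$seed, {
    vapply(seq_len(ncol(inp$x)), function(j) {
      mean(vapply(seq_len(config$permutation_repeats), function(r) {
        xp <- inp$x
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        base_acc - mean(stats::predict(fit, xp) == y)
      }, numeric(1)))
    }, numeric(1))
  })
  new_ranking(colnames(inp$x), pmax(drops, 0), "permutation")
}

#' Rank features with the configured method
#' @inheritParams rank_features_gbdt
#' @return A `vt_ranking`.
#' @export
rank_features <- function(data, config = selector_config()) {
  switch(config$method,
         gbdt_gain = rank_features_gbdt(data, config),
         svc_weight = rank_features_svc(data, config),
         permutation = rank_features_permutation(data, config))
}

#' Select the top N ranked features
#'
#' Ties at the cut are broken by ascending original column index, so a
#' smaller selection is always nested inside a larger one.
#'
#' @param ranking A `vt_ranking`.
#' @param top_n Number of features to keep, `1 <= top_n <= n`.
#' @return Character vector of `top_n` feature names.
#' @export
select_top_n <- function(ranking, top_n) {
  if (top_n < 1 || top_n > nrow(ranking)) {
    stop("top_n must be in [1, ", nrow(ranking), "]", call. = FALSE)
  }
  ranking$feature[seq_len(top_n)]
}
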