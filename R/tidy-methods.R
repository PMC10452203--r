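#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a k-fold evaluation report
#'
#' @param x A `vt_eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per seed x fold: `seed`, `fold`, `auc`,
#'   `precision`, `recall`.
#' @export
tidy.vt_eval_report <- function(x, ...) {
  x$metrics
}

#' One-row summary of a k-fold evaluation report
#'
#' @param x A `vt_eval_report`.
#' @param ... Unused.
#' @return One-row tibble: model, mean and sd of each metric, fold and
#'   seed counts.
#' @export
glance.vt_eval_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    model = x$provenance$model,
    auc = s$mean[s$metric == "auc"], auc_sd = s$sd[s$metric == "auc"],
    precision = s$mean[s$metric == "precision"],
    recall = s$mean[s$metric == "recall"],
    n_folds = max(x$metrics$fold),
    n_seeds = length(unique(x$metrics$seed)))
}

#' Tidy a feature ranking
#'
#' @param x A `vt_ranking`.
#' @param ... Unused.
#' @return The ranking as a plain tibble.
#' @export
tidy.vt_ranking <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot per-fold metrics of an evaluation report
#'
#' @param object A `vt_eval_report`.
#' @param ... Unused.
#' @return A ggplot: one box per metric over the seed x fold scores.
#' @export
autoplot.vt_eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("auc", "precision", "recall"),
                              names_to = "metric", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$score)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4) +
    ggplot2::labs(title = paste("k-fold metrics:", object$provenance$model),
                  x = NULL, y = "score")
}

#' Plot a hyperparameter sweep
#'
#' @param object A `vt_sweep`.
#' @param ... Unused.
#' @return A ggplot line chart of mean AUC (+/- sd ribbon) over the axis.
#' @export
autoplot.vt_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$mean_auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_auc - .data$sd_auc,
                                      ymax = .data$mean_auc + .data$sd_auc),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = object$axis[1], y = "mean ROC-AUC",
                  title = paste("sweep:", object$axis[1], "-",
                                attr(object, "model")))
}

#' Plot top feature importances
#'
#' @param ranking A `vt_ranking`.
#' @param top_n How many features to show.
#' @return A ggplot bar chart.
#' @export
plot_importance <- function(ranking, top_n = 20) {
  top <- utils::head(tibble::as_tibble(ranking), top_n)
  top$feature <- factor(top$feature, levels = rev(top$feature))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = paste0("importance (", attr(ranking, "method"), ")"),
                  y = NULL)
}
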