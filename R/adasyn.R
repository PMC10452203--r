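#' ADASYN oversampling of the minority class
#'
#' Adaptive synthetic sampling: the synthesis budget
#' `G = (m_majority - m_minority) * balance_ratio` is distributed over
#' minority points in proportion to the fraction of majority points among
#' each minority point's K nearest neighbours (Euclidean, over all
#' classes), so synthesis concentrates where the minority class is hardest
#' to learn. Each synthetic point is `x_i + lambda * (x_z - x_i)` with
#' `lambda ~ Uniform(0, 1)` and `x_z` a random minority member of `x_i`'s
#' K-neighbourhood (falling back to the globally nearest minority point
#' when the neighbourhood holds none).
#'
#' @param x Numeric matrix, m samples by n features.
#' @param y Binary labels (0/1) of length m.
#' @param k_neighbors Neighbourhood size K.
#' @param balance_ratio Target fraction beta of the class gap to close;
#'   1 balances the classes fully.
#' @param seed Integer seed; output is deterministic given inputs + seed.
#' @return List with `x` (original rows unchanged and first, synthetic
#'   rows appended), `y`, and `synthetic` (logical marker per row).
#' @export
adasyn_oversample <- function(x, y, k_neighbors = 5, balance_ratio = 1,
                              seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(y),
            k_neighbors >= 1, balance_ratio > 0, balance_ratio <= 1)
  y <- as.integer(y)
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("both classes must be present", call. = FALSE)
  minority <- if (counts[["0"]] <= counts[["1"]]) 0L else 1L
  m_min <- min(counts); m_maj <- max(counts)
  if (m_min < 2) {
    stop("need at least 2 minority points to interpolate", call. = FALSE)
  }
  if (k_neighbors > nrow(x) - 1) {
    stop("k_neighbors (", k_neighbors, ") exceeds available neighbours; ",
         "lower k_neighbors", call. = FALSE)
  }
  G <- round((m_maj - m_min) * balance_ratio)
  if (G == 0) {
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  }

  min_idx <- which(y == minority)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf

  # K nearest neighbours of each minority point, over all classes
  nn_raw <- apply(d[min_idx, , drop = FALSE], 1, function(dr) {
    order(dr)[seq_len(k_neighbors)]
  })
  nn <- if (is.matrix(nn_raw)) t(nn_raw) else matrix(nn_raw, ncol = 1L)
  r <- rowMeans(matrix(y[nn] != minority, nrow = length(min_idx)))
  if (sum(r) == 0) {
    warning("minority class fully isolated from majority; ",
            "spreading the synthesis budget uniformly", call. = FALSE)
    g <- rep(G / length(min_idx), length(min_idx))
  } else {
    g <- r / sum(r) * G
  }
  g <- round(g)

  synth <- withr::with_seed(seed, {
    out <- vector("list", length(min_idx))
    for (ii in seq_along(min_idx)) {
      if (g[ii] == 0) next
      i <- min_idx[ii]
      pool <- nn[ii, ][y[nn[ii, ]] == minority]
      if (length(pool) == 0L) {
        # no minority neighbour in the K-neighbourhood: nearest minority
        others <- setdiff(min_idx, i)
        pool <- others[which.min(d[i, others])]
      }
      z <- pool[sample.int(length(pool), g[ii], replace = TRUE)]
      lam <- stats::runif(g[ii])
      xi <- matrix(x[i, ], g[ii], ncol(x), byrow = TRUE)
      out[[ii]] <- xi + lam * (x[z, , drop = FALSE] - xi)
    }
    do.call(rbind, out)
  })
  if (is.null(synth)) synth <- matrix(0, 0, ncol(x))
  colnames(synth) <- colnames(x)
  list(x = rbind(x, synth),
       y = c(y, rep(minority, nrow(synth))),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(synth))))
}

#' Balance one training fold with ADASYN
#'
#' Oversampling sees only the fold's training rows; test rows never
#' influence synthesis. Synthetic rows carry the sentinel subject id
#' `".synthetic"` so they are recognizably non-real downstream.
#'
#' @param data A `dysphonia_tbl` (features already standardized /
#'   selected as desired).
#' @param plan A `vt_fold_plan`.
#' @param fold Fold index.
#' @inheritParams adasyn_oversample
#' @return List with `x`, `y`, `subject_id` for the augmented training
#'   set and `test` (the untouched test-row indices into `data`).
#' @export
balance_training_fold <- function(data, plan, fold, k_neighbors = 5,
                                  balance_ratio = 1, seed = 1) {
  rows <- fold_rows(data, plan, fold)
  x <- feature_matrix(data)[rows$train, , drop = FALSE]
  y <- data$label[rows$train]
  aug <- adasyn_oversample(x, y, k_neighbors = k_neighbors,
                           balance_ratio = balance_ratio, seed = seed)
  sid <- c(data$subject_id[rows$train],
           rep(".synthetic", sum(aug$synthetic)))
  list(x = aug$x, y = aug$y, subject_id = sid, synthetic = aug$synthetic,
       test = rows$test)
}
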