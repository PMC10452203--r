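#' Vocal tab transformer configuration
#'
#' Architecture hyperparameters of the tabular transformer: each of the
#' `n_features` selected continuous features is embedded by its own small
#' two-layer network into `embed_dim` dimensions, the n embeddings pass
#' through `n_encoders` transformer encoder blocks (`n_heads` attention
#' heads, feed-forward hidden width `rho * embed_dim`, post-norm residual
#' layout), and the flattened `n_features x embed_dim` representation is
#' classified by an MLP head with one hidden layer of width `head_hidden`
#' and a sigmoid output.
#'
#' @param n_features Number of input features n (after selection).
#' @param embed_dim Embedding dimension d; must be divisible by `n_heads`.
#' @param n_encoders Number of stacked encoder blocks L.
#' @param n_heads Attention heads h; key/value dims are `d / h`.
#' @param rho Feed-forward expansion factor (hidden width `rho * d`).
#' @param head_hidden Hidden width of the MLP classification head.
#' @param dropout_p Dropout probability used after the embedder output,
#'   after each residual sublayer, and after the head's hidden layer.
#' @param seed Integer seed for weight initialization.
#' @return A `vt_model_config` list.
#' @export
vocaltab_config <- function(n_features = 96, embed_dim = 64,
                            n_encoders = 6, n_heads = 1, rho = 32,
                            head_hidden = 2048, dropout_p = 0.1,
                            seed = 1) {
  stopifnot(n_features >= 1, embed_dim >= 2, embed_dim %% 2 == 0,
            n_encoders >= 0, n_heads >= 1, embed_dim %% n_heads == 0,
            rho >= 1, head_hidden >= 1, dropout_p >= 0, dropout_p < 1)
  structure(list(n_features = n_features, embed_dim = embed_dim,
                 n_encoders = n_encoders, n_heads = n_heads, rho = rho,
                 head_hidden = head_hidden, dropout_p = dropout_p,
                 seed = seed),
            class = "vt_model_config")
}

#' MLP baseline configuration
#'
#' A plain feed-forward classifier over the raw (standardized, selected)
#' feature vector: fully connected layers with relu activations on every
#' hidden layer, dropout after each hidden layer, and a sigmoid output.
#' The default three hidden widths give four weight layers.
#'
#' @param n_features Input width.
#' @param hidden Integer vector of hidden-layer widths.
#' @param dropout_p Dropout probability after each hidden layer.
#' @param seed Integer seed for weight initialization.
#' @return A `vt_mlp_config` list.
#' @export
mlp_config <- function(n_features, hidden = c(2048, 1280, 1024),
                       dropout_p = 0.1, seed = 1) {
  stopifnot(n_features >= 1, length(hidden) >= 1, all(hidden >= 1),
            dropout_p >= 0, dropout_p < 1)
  structure(list(n_features = n_features, hidden = as.integer(hidden),
                 dropout_p = dropout_p, seed = seed),
            class = "vt_mlp_config")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (final-epoch weights are kept; no early
#'   stopping).
#' @param threshold Probability threshold for precision/recall.
#' @param folds Number of cross-validation folds k.
#' @param seeds Integer vector of run seeds; the k-fold experiment is
#'   repeated once per seed and metrics are reported mean +/- sd.
#' @return A `vt_train_config` list.
#' @export
train_config <- function(learning_rate = 8e-4, batch_size = 32,
                         epochs = 20, threshold = 0.5, folds = 10,
                         seeds = 1:3) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            threshold > 0, threshold < 1, folds >= 2, length(seeds) >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, threshold = threshold, folds = folds,
                 seeds = as.integer(seeds)),
            class = "vt_train_config")
}

#' Count trainable parameters
#'
#' For a transformer configuration the closed form is
#' `n * [(d/2 + d/2) + (d/2 * d + d)]` for the per-feature embedders,
#' `L * [4 (d^2 + d) + (d rho d + rho d) + (rho d * d + d) + 2 * 2d]`
#' for the encoder stack (query/key/value/output projections, the two
#' feed-forward layers, and two trainable layer norms per block), and
#' `(n d H + H) + (H + 1)` for the head with hidden width H. The default
#' configuration (n = 96, d = 64, L = 6, rho = 32, H = 2048) lands at
#' about 14 million.
#'
#' @param config A `vt_model_config` or `vt_mlp_config`.
#' @return Integer-valued count of trainable scalars.
#' @export
count_parameters <- function(config) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.vt_model_config <- function(config) {
  n <- config$n_features; d <- config$embed_dim; L <- config$n_encoders
  H <- config$head_hidden; f <- config$rho * d
  emb <- n * ((d / 2 + d / 2) + (d / 2 * d + d))
  blk <- 4 * (d^2 + d) + (d * f + f) + (f * d + d) + 2 * (2 * d)
  head <- (n * d * H + H) + (H + 1)
  emb + L * blk + head
}

#' @export
count_parameters.vt_mlp_config <- function(config) {
  widths <- c(config$n_features, config$hidden, 1L)
  sum(widths[-length(widths)] * widths[-1] + widths[-1])
}
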