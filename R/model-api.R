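#' Scaled dot-product self-attention
#'
#' `A = softmax(Q K^T / sqrt(k))` row-wise, returned multiplied into `V`.
#' Every row of `A` sums to 1 and all entries lie in (0, 1).
#'
#' @param Q,K Query and key matrices, n x k.
#' @param V Value matrix, n x v.
#' @param return_weights Also return the attention matrix `A`?
#' @return The n x v matrix `A V`, or a list `(output, weights)` when
#'   `return_weights = TRUE`.
#' @export
attention <- function(Q, K, V, return_weights = FALSE) {
  stopifnot(is.matrix(Q), is.matrix(K), is.matrix(V),
            ncol(Q) == ncol(K), nrow(K) == nrow(V), nrow(Q) == nrow(K))
  k <- ncol(Q)
  if (k == 0) stop("key dimension must be positive", call. = FALSE)
  S <- tcrossprod(Q, K) / sqrt(k)
  S <- exp(S - apply(S, 1, max))
  A <- S / rowSums(S)
  out <- A %*% V
  if (return_weights) list(output = out, weights = A) else out
}

#' Initialize an untrained model
#'
#' Builds the full parameter set (fan-in uniform weight initialization,
#' unit layer-norm gains) without any training, for introspection and for
#' running the architecture's building blocks in isolation.
#'
#' @param config A `vt_model_config` or `vt_mlp_config`.
#' @param seed Integer seed (defaults to the config's).
#' @return A `vt_model` or `vt_mlp` with freshly initialized weights and
#'   an empty loss history.
#' @export
init_model <- function(config, seed = config$seed) {
  pars <- withr::with_seed(seed, {
    if (inherits(config, "vt_model_config")) nn_init_vocaltab(config)
    else if (inherits(config, "vt_mlp_config")) nn_init_mlp(config)
    else stop("unknown config class", call. = FALSE)
  })
  structure(list(pars = pars, config = config, loss = numeric(0),
                 seed = seed),
            class = if (inherits(config, "vt_model_config")) "vt_model"
                    else "vt_mlp")
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the config, all weights, and the seed.
#'
#' @param model A `vt_model` or `vt_mlp`.
#' @param path File path.
#' @return `read_checkpoint` returns the model; `write_checkpoint`
#'   returns `path` invisibly.
#' @export
write_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)

#' Train the vocal tab transformer
#'
#' Minibatch Adam on binary cross-entropy for a fixed number of epochs
#' (final-epoch weights kept). Weight initialization, epoch shuffling and
#' dropout are all driven by `seed`, so training is deterministic given
#' the inputs.
#'
#' @param x Numeric matrix of standardized selected features, m x n.
#' @param y Binary labels (1 = PD).
#' @param model_config A `vt_model_config`; its `n_features` must match
#'   `ncol(x)`.
#' @param train_cfg A `vt_train_config`.
#' @param seed Integer seed (defaults to the model config's).
#' @return A `vt_model`: list with `pars`, `config`, `loss` (per-epoch
#'   mean training loss), `seed`.
#' @export
train_model <- function(x, y, model_config = vocaltab_config(ncol(x)),
                        train_cfg = train_config(), seed = model_config$seed) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (ncol(x) != model_config$n_features) {
    stop("ncol(x) != model n_features", call. = FALSE)
  }
  fit <- withr::with_seed(seed, {
    pars <- nn_init_vocaltab(model_config)
    nn_train_loop(pars, model_config, vt_forward_batch, vt_backward_batch,
                  x, as.numeric(y), train_cfg$learning_rate,
                  train_cfg$batch_size, train_cfg$epochs)
  })
  structure(list(pars = fit$pars, config = model_config, loss = fit$loss,
                 seed = seed),
            class = "vt_model")
}

#' Train the MLP baseline
#'
#' @inheritParams train_model
#' @param mlp_cfg A `vt_mlp_config`.
#' @return A `vt_mlp` model object.
#' @export
train_mlp <- function(x, y, mlp_cfg = mlp_config(ncol(x)),
                      train_cfg = train_config(), seed = mlp_cfg$seed) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (ncol(x) != mlp_cfg$n_features) {
    stop("ncol(x) != mlp n_features", call. = FALSE)
  }
  fit <- withr::with_seed(seed, {
    pars <- nn_init_mlp(mlp_cfg)
    nn_train_loop(pars, mlp_cfg, mlp_forward_batch, mlp_backward_batch,
                  x, as.numeric(y), train_cfg$learning_rate,
                  train_cfg$batch_size, train_cfg$epochs)
  })
  structure(list(pars = fit$pars, config = mlp_cfg, loss = fit$loss,
                 seed = seed),
            class = "vt_mlp")
}

#' @export
predict.vt_model <- function(object, newdata, batch_size = 256, ...) {
  stopifnot(is.matrix(newdata))
  p <- numeric(nrow(newdata))
  for (start in seq(1L, nrow(newdata), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nrow(newdata))
    p[idx] <- vt_forward_batch(object$pars, object$config,
                               newdata[idx, , drop = FALSE],
                               training = FALSE)$prob
  }
  p
}

#' @export
predict.vt_mlp <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  mlp_forward_batch(object$pars, object$config, newdata,
                    training = FALSE)$prob
}

#' Number of trainable scalars actually held by a fitted model
#'
#' Introspection counterpart of the closed-form [count_parameters()]; the
#' two must agree exactly.
#'
#' @param model A `vt_model` or `vt_mlp`.
#' @return Integer-valued total length of all parameter arrays.
#' @export
n_trainable <- function(model) {
  sum(vapply(model$pars, length, numeric(1)))
}

#' Embed one sample's features
#'
#' Runs the per-feature embedding networks:
#' `FE_j = Dropout(relu(FC2(relu(FC1(f_j)))))`, each feature through its
#' own two-layer projection, giving one `embed_dim`-vector per feature.
#'
#' @param model A `vt_model`.
#' @param sample Numeric vector of length `n_features`.
#' @param training Apply dropout?
#' @return Matrix `n_features x embed_dim`.
#' @export
embed_features <- function(model, sample, training = FALSE) {
  cfg <- model$config
  stopifnot(length(sample) == cfg$n_features)
  p <- model$pars
  Z1 <- sample * p$emb_W1 + p$emb_b1
  H1 <- relu(Z1)
  E <- matrix(0, cfg$n_features, cfg$embed_dim)
  for (j in seq_len(cfg$n_features)) {
    E[j, ] <- relu(H1[j, ] %*% p$emb_W2[, , j] + p$emb_b2[j, ])
  }
  mask <- drop_mask(nrow(E), ncol(E), cfg$dropout_p, training)
  apply_mask(E, mask)
}

#' Run one encoder block of a fitted model
#'
#' Post-norm residual layout:
#' `E1 = Norm(E + Dropout(MHSA(E)))`,
#' `E_out = Norm(E1 + Dropout(FF(E1)))` with the feed-forward expanding
#' to `rho * embed_dim` and projecting back.
#'
#' @param model A `vt_model`.
#' @param E_in Matrix `n_features x embed_dim` (one sample).
#' @param block Block index in `1:n_encoders`.
#' @param training Apply dropout?
#' @return Matrix of the same shape as `E_in`.
#' @export
encoder_block <- function(model, E_in, block = 1, training = FALSE) {
  cfg <- model$config
  stopifnot(block >= 1, block <= cfg$n_encoders,
            nrow(E_in) == cfg$n_features, ncol(E_in) == cfg$embed_dim)
  cfg1 <- cfg
  cfg1$n_encoders <- 1L
  pars1 <- model$pars[grep("^(emb_|head_)", names(model$pars))]
  px_src <- paste0("blk", block, "_")
  for (nm in grep(paste0("^", px_src), names(model$pars), value = TRUE)) {
    pars1[[sub(px_src, "blk1_", nm)]] <- model$pars[[nm]]
  }
  # reuse the batched path with b = 1 by entering after the embedder:
  one_block_fwd(pars1, cfg1, E_in, training)
}

one_block_fwd <- function(pars, cfg, E, training) {
  n <- nrow(E); d <- ncol(E); h <- cfg$n_heads; dk <- d %/% h
  px <- "blk1_"
  Q <- add_bias(E %*% pars[[paste0(px, "Wq")]], pars[[paste0(px, "bq")]])
  K <- add_bias(E %*% pars[[paste0(px, "Wk")]], pars[[paste0(px, "bk")]])
  V <- add_bias(E %*% pars[[paste0(px, "Wv")]], pars[[paste0(px, "bv")]])
  O <- matrix(0, n, d)
  for (hh in seq_len(h)) {
    cols <- ((hh - 1L) * dk + 1L):(hh * dk)
    O[, cols] <- attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                           V[, cols, drop = FALSE])
  }
  AttnOut <- add_bias(O %*% pars[[paste0(px, "Wo")]], pars[[paste0(px, "bo")]])
  R1 <- E + apply_mask(AttnOut, drop_mask(n, d, cfg$dropout_p, training))
  E1 <- layernorm_fwd(R1, pars[[paste0(px, "g1")]], pars[[paste0(px, "be1")]])$y
  Zf1 <- add_bias(E1 %*% pars[[paste0(px, "Wf1")]], pars[[paste0(px, "bf1")]])
  Zf2 <- add_bias(relu(Zf1) %*% pars[[paste0(px, "Wf2")]],
                  pars[[paste0(px, "bf2")]])
  R2 <- E1 + apply_mask(Zf2, drop_mask(n, d, cfg$dropout_p, training))
  layernorm_fwd(R2, pars[[paste0(px, "g2")]], pars[[paste0(px, "be2")]])$y
}

#' MLP classification head of a fitted model
#'
#' Flattens the `n_features x embed_dim` encoder output row-wise to a
#' single vector, projects to the hidden width with relu (+ dropout in
#' training), then to a single sigmoid probability.
#'
#' @param model A `vt_model`.
#' @param E Encoder output, `n_features x embed_dim`.
#' @param training Apply dropout?
#' @return Probability in (0, 1).
#' @export
mlp_head <- function(model, E, training = FALSE) {
  cfg <- model$config
  stopifnot(nrow(E) == cfg$n_features, ncol(E) == cfg$embed_dim)
  p <- model$pars
  Fv <- as.vector(t(E))
  Zh1 <- drop(Fv %*% p$head_W1) + p$head_b1
  Ah1 <- relu(matrix(Zh1, nrow = 1))
  Dh <- apply_mask(Ah1, drop_mask(1, cfg$head_hidden, cfg$dropout_p,
                                  training))
  sigmoid(drop(Dh %*% p$head_W2) + p$head_b2)
}
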