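# brute-force double-loop softmax attention, kept independent of the
# package's vectorized implementation
ref_attention <- function(Q, K, V) {
  n <- nrow(Q); k <- ncol(Q)
  A <- matrix(0, n, nrow(K))
  for (i in seq_len(n)) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(k)
    e <- exp(s - max(s))
    A[i, ] <- e / sum(e)
  }
  A %*% V
}

test_that("attention equals the brute-force oracle and normalizes rows", {
  withr::with_seed(11, {
    for (rep in 1:100) {
      n <- sample(1:6, 1); k <- sample(1:5, 1); v <- sample(1:5, 1)
      Q <- matrix(rnorm(n * k), n, k)
      K <- matrix(rnorm(n * k), n, k)
      V <- matrix(rnorm(n * v), n, v)
      out <- attention(Q, K, V, return_weights = TRUE)
      expect_equal(out$output, ref_attention(Q, K, V), tolerance = 1e-6)
      expect_equal(unname(rowSums(out$weights)), rep(1, n), tolerance = 1e-6)
      expect_true(all(out$weights > 0 & out$weights < 1 | n == 1))
    }
  })
  # n = 1: A = [[1]], output = V exactly
  out <- attention(matrix(2, 1, 3), matrix(1, 1, 3), matrix(5, 1, 2))
  expect_equal(out, matrix(5, 1, 2))
  # identical rows -> uniform attention -> column means of V
  Q <- matrix(1, 4, 2); K <- matrix(2, 4, 2)
  V <- matrix(rnorm(8), 4, 2)
  expect_equal(attention(Q, K, V),
               matrix(colMeans(V), 4, 2, byrow = TRUE), tolerance = 1e-12)
  expect_error(attention(matrix(0, 2, 0), matrix(0, 2, 0), matrix(1, 2, 1)),
               "key dimension")
})

test_that("per-feature embedder matches a pencil-and-paper relu chain", {
  cfg <- vocaltab_config(n_features = 1, embed_dim = 2, n_encoders = 0,
                         head_hidden = 2, rho = 1, dropout_p = 0, seed = 1)
  model <- init_model(cfg)
  model$pars$emb_W1 <- matrix(2, 1, 1)
  model$pars$emb_b1 <- matrix(0.5, 1, 1)
  model$pars$emb_W2 <- array(c(1, -1), c(1, 2, 1))
  model$pars$emb_b2 <- matrix(c(0.1, 0.2), 1, 2)
  # f = 1.5: FC1 -> 3.5, relu -> 3.5; FC2 -> (3.6, -3.3), relu -> (3.6, 0)
  expect_equal(embed_features(model, 1.5), matrix(c(3.6, 0), 1, 2))
  # negative pre-activation dies at FC1: f = -1 -> relu(-1.5) = 0 ->
  # relu(b2) = (0.1, 0.2)
  expect_equal(embed_features(model, -1), matrix(c(0.1, 0.2), 1, 2))

  # all-zero weights and biases give all-zero embeddings
  cfg8 <- vocaltab_config(n_features = 3, embed_dim = 8, n_encoders = 0,
                          rho = 1, head_hidden = 4, dropout_p = 0, seed = 2)
  m0 <- init_model(cfg8)
  for (nm in c("emb_W1", "emb_b1", "emb_W2", "emb_b2")) {
    m0$pars[[nm]][] <- 0
  }
  expect_equal(embed_features(m0, c(1, -2, 3)), matrix(0, 3, 8))
  # shape: n x embed_dim, each row from its own embedder
  m <- init_model(cfg8)
  E <- embed_features(m, c(1, 2, 3))
  expect_equal(dim(E), c(3, 8))
  E2 <- embed_features(m, c(1, 2, 99))
  expect_equal(E[1:2, ], E2[1:2, ])   # feature 3 change leaves rows 1-2
  expect_false(isTRUE(all.equal(E[3, ], E2[3, ])))
})

test_that("encoder block matches an independent step-by-step computation", {
  cfg <- vocaltab_config(n_features = 3, embed_dim = 4, n_encoders = 1,
                         n_heads = 1, rho = 2, head_hidden = 8,
                         dropout_p = 0, seed = 9)
  model <- init_model(cfg)
  p <- model$pars
  withr::with_seed(1, E0 <- matrix(rnorm(12), 3, 4))

  ln_ref <- function(x, g, b, eps = 1e-5) {
    t(apply(x, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) * g + b
    }))
  }
  Q <- sweep(E0 %*% p$blk1_Wq, 2, p$blk1_bq, "+")
  K <- sweep(E0 %*% p$blk1_Wk, 2, p$blk1_bk, "+")
  V <- sweep(E0 %*% p$blk1_Wv, 2, p$blk1_bv, "+")
  O <- ref_attention(Q, K, V)
  R1 <- E0 + sweep(O %*% p$blk1_Wo, 2, p$blk1_bo, "+")
  E1 <- ln_ref(R1, p$blk1_g1, p$blk1_be1)
  FF <- pmax(sweep(E1 %*% p$blk1_Wf1, 2, p$blk1_bf1, "+"), 0)
  R2 <- E1 + sweep(FF %*% p$blk1_Wf2, 2, p$blk1_bf2, "+")
  expected <- ln_ref(R2, p$blk1_g2, p$blk1_be2)

  expect_equal(encoder_block(model, E0, block = 1), expected,
               tolerance = 1e-10)
})

test_that("zero sublayer weights leave the (normalized) input unchanged", {
  cfg <- vocaltab_config(n_features = 4, embed_dim = 6, n_encoders = 1,
                         rho = 2, head_hidden = 8, dropout_p = 0, seed = 3)
  model <- init_model(cfg)
  for (nm in grep("^blk1_(W|b)", names(model$pars), value = TRUE)) {
    model$pars[[nm]][] <- 0
  }
  withr::with_seed(2, E0 <- matrix(rnorm(24), 4, 6))
  out <- encoder_block(model, E0)
  # residual path carries the input; only the two norms act on it
  ln1 <- function(x, eps = 1e-5) {
    mu <- rowMeans(x)
    (x - mu) / sqrt(rowMeans((x - mu)^2) + eps)
  }
  expect_equal(out, ln1(ln1(E0)), tolerance = 1e-10)
  # output shape equals input shape for any stack depth
  for (L in c(1, 3, 8)) {
    cfgL <- vocaltab_config(n_features = 4, embed_dim = 6, n_encoders = L,
                            rho = 2, head_hidden = 8, seed = 4)
    mL <- init_model(cfgL)
    X <- matrix(rnorm(8), 2, 4)
    expect_length(predict(mL, X), 2)
  }
})

test_that("mlp head flattens, saturates in (0,1), and is 0.5 at zero weights", {
  cfg <- vocaltab_config(n_features = 5, embed_dim = 4, n_encoders = 0,
                         rho = 1, head_hidden = 7, dropout_p = 0, seed = 5)
  model <- init_model(cfg)
  expect_equal(dim(model$pars$head_W1), c(20, 7))
  withr::with_seed(3, E <- matrix(rnorm(20), 5, 4))
  p <- mlp_head(model, E)
  expect_gt(p, 0); expect_lt(p, 1)
  model$pars$head_W2[] <- 0
  model$pars$head_b2[] <- 0
  expect_equal(mlp_head(model, E), 0.5)
  # default architecture: flatten 96*64 = 6144 -> 2048
  expect_equal(dim(init_model(vocaltab_config(n_encoders = 0))$pars$head_W1),
               c(6144, 2048))
})

test_that("eval-mode forward is deterministic and batch-shaped", {
  cfg <- vocaltab_config(n_features = 6, embed_dim = 8, n_encoders = 2,
                         rho = 2, head_hidden = 16, seed = 6)
  model <- init_model(cfg)
  withr::with_seed(4, X <- matrix(rnorm(32 * 6), 32, 6))
  p1 <- predict(model, X)
  p2 <- predict(model, X)
  expect_identical(p1, p2)
  expect_length(p1, 32)
  expect_true(all(p1 > 0 & p1 < 1))
  # batched and single-sample paths agree
  p_single <- predict(model, X[5, , drop = FALSE])
  expect_equal(p1[5], p_single, tolerance = 1e-12)
  expect_error(predict(model, X[, 1:4]), "n")
})

test_that("closed-form parameter count equals introspection", {
  # pencil arithmetic: L = 0, n = 1, d = 2, H = 2, rho = 1
  # emb: 1*[(1+1) + (1*2+2)] = 6; head: (1*2*2+2) + (2+1) = 9
  cfg0 <- vocaltab_config(n_features = 1, embed_dim = 2, n_encoders = 0,
                          rho = 1, head_hidden = 2)
  expect_equal(count_parameters(cfg0), 15)
  expect_equal(n_trainable(init_model(cfg0)), 15)

  withr::with_seed(21, {
    for (i in 1:20) {
      h <- sample(c(1, 2, 4), 1)
      cfg <- vocaltab_config(n_features = sample(2:8, 1),
                             embed_dim = h * 2 * sample(1:3, 1),
                             n_encoders = sample(0:3, 1), n_heads = h,
                             rho = sample(1:4, 1),
                             head_hidden = sample(2:32, 1))
      expect_equal(n_trainable(init_model(cfg)), count_parameters(cfg))
    }
  })
  # doubling H approximately doubles only the head's contribution
  c1 <- vocaltab_config(head_hidden = 2048)
  c2 <- vocaltab_config(head_hidden = 4096)
  head1 <- (96 * 64 * 2048 + 2048) + 2049
  head2 <- (96 * 64 * 4096 + 4096) + 4097
  expect_equal(count_parameters(c2) - count_parameters(c1), head2 - head1)
  # mlp closed form vs introspection
  mcfg <- mlp_config(25, hidden = c(10, 5))
  expect_equal(count_parameters(mcfg),
               25 * 10 + 10 + 10 * 5 + 5 + 5 + 1)
  expect_equal(n_trainable(init_model(mcfg)), count_parameters(mcfg))
})

test_that("training reduces loss, fits strong signal, and is seed-stable", {
  withr::with_seed(8, {
    x <- rbind(matrix(rnorm(60 * 4), 60, 4) + 1.5,
               matrix(rnorm(60 * 4), 60, 4))
  })
  y <- rep(c(1, 0), each = 60)
  cfg <- vocaltab_config(n_features = 4, embed_dim = 8, n_encoders = 1,
                         rho = 2, head_hidden = 8, seed = 2)
  tcfg <- train_config(epochs = 6, folds = 2)
  fit <- train_model(x, y, cfg, tcfg, seed = 2)
  expect_lt(utils::tail(fit$loss, 1), fit$loss[1])
  expect_gt(roc_auc(predict(fit, x), y), 0.95)
  fit2 <- train_model(x, y, cfg, tcfg, seed = 2)
  expect_identical(fit$loss, fit2$loss)
  expect_identical(fit$pars, fit2$pars)
  expect_error(train_model(x, rep(1, 120), cfg, tcfg), "both classes")
  # checkpoint round trip
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(fit, path)
  expect_equal(predict(read_checkpoint(path), x), predict(fit, x))
})
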