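# Neural-network internals: dense algebra, batched transformer forward /
# backward, and Adam. Activations live in (b*n) x d matrices laid out
# sample-major (rows (i-1)*n + 1:n belong to sample i), so dense layers are
# single BLAS matmuls and only the n x n attention products loop over the
# batch.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(z) 1 / (1 + exp(-z))

add_bias <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

# inverted dropout; returns the scaled mask (or NULL in eval mode)
drop_mask <- function(dim1, dim2, p, training) {
  if (!training || p == 0) return(NULL)
  matrix((stats::runif(dim1 * dim2) >= p) / (1 - p), dim1, dim2)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# fan-in uniform init, U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for weights and bias
init_dense <- function(fan_in, fan_out) {
  b <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out),
       b = stats::runif(fan_out, -b, b))
}

LN_EPS <- 1e-5

layernorm_fwd <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  sig <- sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc / sig
  y <- add_bias(xhat * matrix(gamma, nrow(x), ncol(x), byrow = TRUE), beta)
  list(y = y, xhat = xhat, sig = sig)
}

layernorm_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * matrix(gamma, nrow(dy), ncol(dy), byrow = TRUE)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sig
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- parameter initialization -------------------------------------------

nn_init_vocaltab <- function(cfg) {
  n <- cfg$n_features; d <- cfg$embed_dim; d2 <- d / 2L
  H <- cfg$head_hidden; f <- cfg$rho * d
  pars <- list()
  # per-feature embedders: FC1 (1 -> d/2) rows, FC2 (d/2 -> d) slabs
  pars$emb_W1 <- matrix(stats::runif(n * d2, -1, 1), n, d2)
  pars$emb_b1 <- matrix(stats::runif(n * d2, -1, 1), n, d2)
  bw <- 1 / sqrt(d2)
  pars$emb_W2 <- array(stats::runif(d2 * d * n, -bw, bw), c(d2, d, n))
  pars$emb_b2 <- matrix(stats::runif(n * d, -bw, bw), n, d)
  for (l in seq_len(cfg$n_encoders)) {
    px <- paste0("blk", l, "_")
    for (nm in c("q", "k", "v", "o")) {
      dn <- init_dense(d, d)
      pars[[paste0(px, "W", nm)]] <- dn$W
      pars[[paste0(px, "b", nm)]] <- dn$b
    }
    dn <- init_dense(d, f)
    pars[[paste0(px, "Wf1")]] <- dn$W; pars[[paste0(px, "bf1")]] <- dn$b
    dn <- init_dense(f, d)
    pars[[paste0(px, "Wf2")]] <- dn$W; pars[[paste0(px, "bf2")]] <- dn$b
    pars[[paste0(px, "g1")]] <- rep(1, d); pars[[paste0(px, "be1")]] <- rep(0, d)
    pars[[paste0(px, "g2")]] <- rep(1, d); pars[[paste0(px, "be2")]] <- rep(0, d)
  }
  dn <- init_dense(n * d, H)
  pars$head_W1 <- dn$W; pars$head_b1 <- dn$b
  dn <- init_dense(H, 1L)
  pars$head_W2 <- dn$W; pars$head_b2 <- dn$b
  pars
}

# ---- transformer forward ------------------------------------------------

# X: b x n batch of standardized feature values. Returns logits plus the
# caches backprop needs when training = TRUE.
vt_forward_batch <- function(pars, cfg, X, training = FALSE,
                             keep_cache = training) {
  b <- nrow(X); n <- cfg$n_features; d <- cfg$embed_dim; d2 <- d / 2L
  h <- cfg$n_heads; dk <- d %/% h
  stopifnot(ncol(X) == n)
  jrep <- rep(seq_len(n), times = b)
  Xv <- as.vector(t(X))

  Z1 <- Xv * pars$emb_W1[jrep, , drop = FALSE] +
    pars$emb_b1[jrep, , drop = FALSE]
  H1 <- relu(Z1)
  Z2 <- matrix(0, b * n, d)
  for (j in seq_len(n)) {
    rj <- seq(j, b * n, by = n)
    Z2[rj, ] <- add_bias(H1[rj, , drop = FALSE] %*% pars$emb_W2[, , j],
                         pars$emb_b2[j, ])
  }
  A2 <- relu(Z2)
  m_emb <- drop_mask(b * n, d, cfg$dropout_p, training)
  E <- apply_mask(A2, m_emb)

  blocks <- vector("list", cfg$n_encoders)
  for (l in seq_len(cfg$n_encoders)) {
    px <- paste0("blk", l, "_")
    E_in <- E
    Q <- add_bias(E %*% pars[[paste0(px, "Wq")]], pars[[paste0(px, "bq")]])
    K <- add_bias(E %*% pars[[paste0(px, "Wk")]], pars[[paste0(px, "bk")]])
    V <- add_bias(E %*% pars[[paste0(px, "Wv")]], pars[[paste0(px, "bv")]])
    O <- matrix(0, b * n, d)
    Amats <- if (keep_cache) vector("list", b * h)
    for (i in seq_len(b)) {
      rows <- ((i - 1L) * n + 1L):(i * n)
      for (hh in seq_len(h)) {
        cols <- ((hh - 1L) * dk + 1L):(hh * dk)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dk)
        S <- exp(S - apply(S, 1, max))
        A <- S / rowSums(S)
        O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
        if (keep_cache) Amats[[(i - 1L) * h + hh]] <- A
      }
    }
    AttnOut <- add_bias(O %*% pars[[paste0(px, "Wo")]],
                        pars[[paste0(px, "bo")]])
    m1 <- drop_mask(b * n, d, cfg$dropout_p, training)
    R1 <- E + apply_mask(AttnOut, m1)
    ln1 <- layernorm_fwd(R1, pars[[paste0(px, "g1")]],
                         pars[[paste0(px, "be1")]])
    E1 <- ln1$y
    Zf1 <- add_bias(E1 %*% pars[[paste0(px, "Wf1")]],
                    pars[[paste0(px, "bf1")]])
    Af1 <- relu(Zf1)
    Zf2 <- add_bias(Af1 %*% pars[[paste0(px, "Wf2")]],
                    pars[[paste0(px, "bf2")]])
    m2 <- drop_mask(b * n, d, cfg$dropout_p, training)
    R2 <- E1 + apply_mask(Zf2, m2)
    ln2 <- layernorm_fwd(R2, pars[[paste0(px, "g2")]],
                         pars[[paste0(px, "be2")]])
    if (keep_cache) {
      blocks[[l]] <- list(E_in = E_in, Q = Q, K = K, V = V, O = O,
                          Amats = Amats, m1 = m1, ln1 = ln1, E1 = E1,
                          Zf1 = Zf1, Af1 = Af1, m2 = m2, ln2 = ln2)
    }
    E <- ln2$y
  }

  Fm <- matrix(as.vector(t(E)), nrow = b, byrow = TRUE)
  Zh1 <- add_bias(Fm %*% pars$head_W1, pars$head_b1)
  Ah1 <- relu(Zh1)
  mh <- drop_mask(b, cfg$head_hidden, cfg$dropout_p, training)
  Dh <- apply_mask(Ah1, mh)
  logit <- drop(add_bias(Dh %*% pars$head_W2, pars$head_b2))

  cache <- if (keep_cache) {
    list(X = X, jrep = jrep, Xv = Xv, Z1 = Z1, H1 = H1, Z2 = Z2,
         m_emb = m_emb, blocks = blocks, E_final = E, Fm = Fm, Zh1 = Zh1,
         mh = mh, Dh = Dh, b = b)
  }
  list(logit = logit, prob = sigmoid(logit), cache = cache)
}

# ---- transformer backward -----------------------------------------------

vt_backward_batch <- function(pars, cfg, cache, dlogit) {
  b <- cache$b; n <- cfg$n_features; d <- cfg$embed_dim
  h <- cfg$n_heads; dk <- d %/% h
  g <- list()

  dlogit <- matrix(dlogit, ncol = 1)
  g$head_W2 <- crossprod(cache$Dh, dlogit)
  g$head_b2 <- sum(dlogit)
  dDh <- tcrossprod(dlogit, pars$head_W2)
  dAh1 <- apply_mask(dDh, cache$mh)
  dZh1 <- dAh1 * (cache$Zh1 > 0)
  g$head_W1 <- crossprod(cache$Fm, dZh1)
  g$head_b1 <- colSums(dZh1)
  dF <- tcrossprod(dZh1, pars$head_W1)
  dE <- matrix(as.vector(t(dF)), ncol = d, byrow = TRUE)

  for (l in rev(seq_len(cfg$n_encoders))) {
    px <- paste0("blk", l, "_")
    ck <- cache$blocks[[l]]
    ln2b <- layernorm_bwd(dE, ck$ln2, pars[[paste0(px, "g2")]])
    g[[paste0(px, "g2")]] <- ln2b$dgamma
    g[[paste0(px, "be2")]] <- ln2b$dbeta
    dR2 <- ln2b$dx
    dE1 <- dR2
    dZf2 <- apply_mask(dR2, ck$m2)
    g[[paste0(px, "Wf2")]] <- crossprod(ck$Af1, dZf2)
    g[[paste0(px, "bf2")]] <- colSums(dZf2)
    dAf1 <- tcrossprod(dZf2, pars[[paste0(px, "Wf2")]])
    dZf1 <- dAf1 * (ck$Zf1 > 0)
    g[[paste0(px, "Wf1")]] <- crossprod(ck$E1, dZf1)
    g[[paste0(px, "bf1")]] <- colSums(dZf1)
    dE1 <- dE1 + tcrossprod(dZf1, pars[[paste0(px, "Wf1")]])
    ln1b <- layernorm_bwd(dE1, ck$ln1, pars[[paste0(px, "g1")]])
    g[[paste0(px, "g1")]] <- ln1b$dgamma
    g[[paste0(px, "be1")]] <- ln1b$dbeta
    dR1 <- ln1b$dx
    dE <- dR1  # residual path into the block input
    dAttnOut <- apply_mask(dR1, ck$m1)
    g[[paste0(px, "Wo")]] <- crossprod(ck$O, dAttnOut)
    g[[paste0(px, "bo")]] <- colSums(dAttnOut)
    dO <- tcrossprod(dAttnOut, pars[[paste0(px, "Wo")]])
    dQ <- matrix(0, b * n, d); dK <- matrix(0, b * n, d)
    dV <- matrix(0, b * n, d)
    for (i in seq_len(b)) {
      rows <- ((i - 1L) * n + 1L):(i * n)
      for (hh in seq_len(h)) {
        cols <- ((hh - 1L) * dk + 1L):(hh * dk)
        A <- ck$Amats[[(i - 1L) * h + hh]]
        dOb <- dO[rows, cols, drop = FALSE]
        Vb <- ck$V[rows, cols, drop = FALSE]
        dA <- tcrossprod(dOb, Vb)
        dV[rows, cols] <- crossprod(A, dOb)
        dS <- A * (dA - rowSums(A * dA)) / sqrt(dk)
        dQ[rows, cols] <- dS %*% ck$K[rows, cols, drop = FALSE]
        dK[rows, cols] <- crossprod(dS, ck$Q[rows, cols, drop = FALSE])
      }
    }
    E_in <- ck$E_in
    g[[paste0(px, "Wq")]] <- crossprod(E_in, dQ)
    g[[paste0(px, "bq")]] <- colSums(dQ)
    g[[paste0(px, "Wk")]] <- crossprod(E_in, dK)
    g[[paste0(px, "bk")]] <- colSums(dK)
    g[[paste0(px, "Wv")]] <- crossprod(E_in, dV)
    g[[paste0(px, "bv")]] <- colSums(dV)
    dE <- dE + tcrossprod(dQ, pars[[paste0(px, "Wq")]]) +
      tcrossprod(dK, pars[[paste0(px, "Wk")]]) +
      tcrossprod(dV, pars[[paste0(px, "Wv")]])
  }

  dA2 <- apply_mask(dE, cache$m_emb)
  dZ2 <- dA2 * (cache$Z2 > 0)
  dH1 <- matrix(0, b * n, d / 2L)
  gW2 <- array(0, dim(pars$emb_W2))
  gb2 <- matrix(0, n, d)
  for (j in seq_len(n)) {
    rj <- seq(j, b * n, by = n)
    gW2[, , j] <- crossprod(cache$H1[rj, , drop = FALSE],
                            dZ2[rj, , drop = FALSE])
    gb2[j, ] <- colSums(dZ2[rj, , drop = FALSE])
    dH1[rj, ] <- tcrossprod(dZ2[rj, , drop = FALSE], pars$emb_W2[, , j])
  }
  g$emb_W2 <- gW2; g$emb_b2 <- gb2
  dZ1 <- dH1 * (cache$Z1 > 0)
  g$emb_W1 <- rowsum(dZ1 * cache$Xv, cache$jrep)
  g$emb_b1 <- rowsum(dZ1, cache$jrep)
  g
}

# ---- MLP baseline forward/backward --------------------------------------

nn_init_mlp <- function(cfg) {
  widths <- c(cfg$n_features, cfg$hidden, 1L)
  pars <- list()
  for (l in seq_len(length(widths) - 1L)) {
    dn <- init_dense(widths[l], widths[l + 1L])
    pars[[paste0("W", l)]] <- dn$W
    pars[[paste0("b", l)]] <- dn$b
  }
  pars
}

mlp_forward_batch <- function(pars, cfg, X, training = FALSE,
                              keep_cache = training) {
  nl <- length(cfg$hidden) + 1L
  A <- X
  Zs <- vector("list", nl); As <- vector("list", nl)
  masks <- vector("list", nl)
  for (l in seq_len(nl)) {
    As[[l]] <- A
    Z <- add_bias(A %*% pars[[paste0("W", l)]], pars[[paste0("b", l)]])
    Zs[[l]] <- Z
    if (l < nl) {
      A <- relu(Z)
      masks[l] <- list(drop_mask(nrow(A), ncol(A), cfg$dropout_p, training))
      A <- apply_mask(A, masks[[l]])
    }
  }
  logit <- drop(Zs[[nl]])
  cache <- if (keep_cache) list(Zs = Zs, As = As, masks = masks, nl = nl)
  list(logit = logit, prob = sigmoid(logit), cache = cache)
}

mlp_backward_batch <- function(pars, cfg, cache, dlogit) {
  nl <- cache$nl
  g <- list()
  dZ <- matrix(dlogit, ncol = 1)
  for (l in rev(seq_len(nl))) {
    g[[paste0("W", l)]] <- crossprod(cache$As[[l]], dZ)
    g[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) {
      dA <- tcrossprod(dZ, pars[[paste0("W", l)]])
      dA <- apply_mask(dA, cache$masks[[l - 1L]])
      dZ <- dA * (cache$Zs[[l - 1L]] > 0)
    }
  }
  g
}

# ---- Adam + training loop -----------------------------------------------

adam_step <- function(pars, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(pars)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    pars[[nm]] <- pars[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(pars = pars, state = state)
}

bce_from_logit <- function(logit, y) {
  mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
}

# shared minibatch Adam loop over a forward/backward pair
nn_train_loop <- function(pars, cfg, fwd, bwd, x, y, lr, batch_size,
                          epochs) {
  state <- list(t = 0L,
                m = lapply(pars, function(p) p * 0),
                v = lapply(pars, function(p) p * 0))
  m <- nrow(x)
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(m)
    losses <- c()
    for (start in seq(1L, m, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, m)]
      Xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- fwd(pars, cfg, Xb, training = TRUE)
      losses <- c(losses, bce_from_logit(fw$logit, yb))
      dlogit <- (fw$prob - yb) / length(yb)
      grads <- bwd(pars, cfg, fw$cache, dlogit)
      upd <- adam_step(pars, grads, state, lr)
      pars <- upd$pars; state <- upd$state
    }
    loss_hist[ep] <- mean(losses)
  }
  list(pars = pars, loss = loss_hist)
}
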