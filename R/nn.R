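# Minimal dense neural-net kernels used by both branches.
# All functions are pure; parameters and gradients travel as named lists of
# numeric matrices/vectors. Shapes follow the "rows = time steps" convention.

add_bias <- function(M, b) M + rep(b, each = nrow(M))

row_softmax <- function(S) {
  mx <- apply(S, 1, max)
  E <- exp(S - mx)            # vector recycles down columns = per-row shift
  E / rowSums(E)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

LN_EPS <- 1e-5

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(Y = add_bias(t(t(xhat) * g), b), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dY) {
  xhat <- cache$xhat
  dxhat <- t(t(dY) * g)
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dX = dX, dg = dg, db = db)
}

softmax_ce <- function(logits, y) {
  mx <- max(logits)
  lse <- mx + log(sum(exp(logits - mx)))
  probs <- exp(logits - lse)
  d <- probs
  d[y] <- d[y] - 1
  list(loss = lse - logits[y], probs = probs, dlogits = d)
}

init_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

# ---- transformer encoder ---------------------------------------------------

encoder_hp <- function(vocab_size, hidden = 32L, layers = 2L, heads = 2L,
                       ff = 64L, max_length = 256L) {
  stopifnot(hidden %% heads == 0)
  list(vocab_size = as.integer(vocab_size), hidden = as.integer(hidden),
       layers = as.integer(layers), heads = as.integer(heads),
       ff = as.integer(ff), max_length = as.integer(max_length),
       dh = as.integer(hidden / heads))
}

encoder_init <- function(hp) {
  h <- hp$hidden
  p <- list(
    tok_emb = init_mat(hp$vocab_size, h),
    pos_emb = init_mat(hp$max_length, h)
  )
  for (l in seq_len(hp$layers)) {
    nm <- function(s) paste0("l", l, "_", s)
    p[[nm("Wq")]] <- init_mat(h, h); p[[nm("bq")]] <- numeric(h)
    p[[nm("Wk")]] <- init_mat(h, h); p[[nm("bk")]] <- numeric(h)
    p[[nm("Wv")]] <- init_mat(h, h); p[[nm("bv")]] <- numeric(h)
    p[[nm("Wo")]] <- init_mat(h, h); p[[nm("bo")]] <- numeric(h)
    p[[nm("ln1_g")]] <- rep(1, h);   p[[nm("ln1_b")]] <- numeric(h)
    p[[nm("W1")]] <- init_mat(h, hp$ff); p[[nm("b1")]] <- numeric(hp$ff)
    p[[nm("W2")]] <- init_mat(hp$ff, h); p[[nm("b2")]] <- numeric(h)
    p[[nm("ln2_g")]] <- rep(1, h);   p[[nm("ln2_b")]] <- numeric(h)
  }
  p
}

encoder_forward <- function(p, ids, hp) {
  T_ <- length(ids)
  if (T_ > hp$max_length) {
    stop("sequence length ", T_, " exceeds encoder limit ", hp$max_length,
         call. = FALSE)
  }
  X <- p$tok_emb[ids, , drop = FALSE] + p$pos_emb[seq_len(T_), , drop = FALSE]
  caches <- vector("list", hp$layers)
  s <- sqrt(hp$dh)
  for (l in seq_len(hp$layers)) {
    nm <- function(x) paste0("l", l, "_", x)
    X_in <- X
    Q <- add_bias(X %*% p[[nm("Wq")]], p[[nm("bq")]])
    K <- add_bias(X %*% p[[nm("Wk")]], p[[nm("bk")]])
    V <- add_bias(X %*% p[[nm("Wv")]], p[[nm("bv")]])
    O <- matrix(0, T_, hp$hidden)
    A_list <- vector("list", hp$heads)
    for (j in seq_len(hp$heads)) {
      idx <- ((j - 1L) * hp$dh + 1L):(j * hp$dh)
      A <- row_softmax(tcrossprod(Q[, idx, drop = FALSE],
                                  K[, idx, drop = FALSE]) / s)
      A_list[[j]] <- A
      O[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    M <- add_bias(O %*% p[[nm("Wo")]], p[[nm("bo")]])
    R1 <- X_in + M
    ln1 <- layernorm_fwd(R1, p[[nm("ln1_g")]], p[[nm("ln1_b")]])
    X1 <- ln1$Y
    P1 <- add_bias(X1 %*% p[[nm("W1")]], p[[nm("b1")]])
    G1 <- gelu(P1)
    P2 <- add_bias(G1 %*% p[[nm("W2")]], p[[nm("b2")]])
    R2 <- X1 + P2
    ln2 <- layernorm_fwd(R2, p[[nm("ln2_g")]], p[[nm("ln2_b")]])
    caches[[l]] <- list(X_in = X_in, Q = Q, K = K, V = V, O = O,
                        A = A_list, ln1 = ln1, X1 = X1, P1 = P1, G1 = G1,
                        ln2 = ln2)
    X <- ln2$Y
  }
  list(X = X, caches = caches, ids = ids, T_ = T_)
}

encoder_backward <- function(p, fwd, hp, dX) {
  g <- list()
  s <- sqrt(hp$dh)
  for (l in rev(seq_len(hp$layers))) {
    nm <- function(x) paste0("l", l, "_", x)
    cc <- fwd$caches[[l]]
    b2 <- layernorm_bwd(cc$ln2, p[[nm("ln2_g")]], dX)
    g[[nm("ln2_g")]] <- b2$dg; g[[nm("ln2_b")]] <- b2$db
    dR2 <- b2$dX
    dX1 <- dR2
    dP2 <- dR2
    g[[nm("W2")]] <- crossprod(cc$G1, dP2)
    g[[nm("b2")]] <- colSums(dP2)
    dG1 <- tcrossprod(dP2, p[[nm("W2")]])
    dP1 <- dG1 * gelu_grad(cc$P1)
    g[[nm("W1")]] <- crossprod(cc$X1, dP1)
    g[[nm("b1")]] <- colSums(dP1)
    dX1 <- dX1 + tcrossprod(dP1, p[[nm("W1")]])
    b1 <- layernorm_bwd(cc$ln1, p[[nm("ln1_g")]], dX1)
    g[[nm("ln1_g")]] <- b1$dg; g[[nm("ln1_b")]] <- b1$db
    dR1 <- b1$dX
    dXin <- dR1
    dM <- dR1
    g[[nm("Wo")]] <- crossprod(cc$O, dM)
    g[[nm("bo")]] <- colSums(dM)
    dO <- tcrossprod(dM, p[[nm("Wo")]])
    dQ <- matrix(0, fwd$T_, hp$hidden)
    dK <- matrix(0, fwd$T_, hp$hidden)
    dV <- matrix(0, fwd$T_, hp$hidden)
    for (j in seq_len(hp$heads)) {
      idx <- ((j - 1L) * hp$dh + 1L):(j * hp$dh)
      A <- cc$A[[j]]
      dOj <- dO[, idx, drop = FALSE]
      Vj <- cc$V[, idx, drop = FALSE]
      dA <- tcrossprod(dOj, Vj)
      dV[, idx] <- crossprod(A, dOj)
      dS <- A * (dA - rowSums(dA * A)) / s
      dQ[, idx] <- dS %*% cc$K[, idx, drop = FALSE]
      dK[, idx] <- crossprod(dS, cc$Q[, idx, drop = FALSE])
    }
    g[[nm("Wq")]] <- crossprod(cc$X_in, dQ); g[[nm("bq")]] <- colSums(dQ)
    g[[nm("Wk")]] <- crossprod(cc$X_in, dK); g[[nm("bk")]] <- colSums(dK)
    g[[nm("Wv")]] <- crossprod(cc$X_in, dV); g[[nm("bv")]] <- colSums(dV)
    dXin <- dXin + tcrossprod(dQ, p[[nm("Wq")]]) +
      tcrossprod(dK, p[[nm("Wk")]]) + tcrossprod(dV, p[[nm("Wv")]])
    dX <- dXin
  }
  # embedding gradients: scatter-add token rows, slice position rows
  dtok <- matrix(0, hp$vocab_size, hp$hidden)
  agg <- rowsum(dX, group = fwd$ids)
  dtok[as.integer(rownames(agg)), ] <- agg
  dpos <- matrix(0, hp$max_length, hp$hidden)
  dpos[seq_len(fwd$T_), ] <- dX
  g$tok_emb <- dtok
  g$pos_emb <- dpos
  g
}

# ---- 1-D convolutional head ------------------------------------------------

cnn_head_hp <- function(d_in, kernel_sizes = c(2L, 3L, 4L), filters = 2L,
                        n_classes = 4L) {
  list(d_in = as.integer(d_in), kernel_sizes = as.integer(kernel_sizes),
       filters = as.integer(filters), n_classes = as.integer(n_classes),
       pooled_dim = as.integer(length(kernel_sizes) * filters))
}

cnn_head_init <- function(hp) {
  p <- list()
  for (k in hp$kernel_sizes) {
    fan <- k * hp$d_in
    p[[paste0("convW", k)]] <- init_mat(fan, hp$filters, sd = sqrt(2 / fan))
    p[[paste0("convb", k)]] <- numeric(hp$filters)
  }
  p$W_out <- init_mat(hp$pooled_dim, hp$n_classes,
                      sd = sqrt(2 / hp$pooled_dim))
  p$b_out <- numeric(hp$n_classes)
  p
}

im2col <- function(X, k) {
  Tk <- nrow(X) - k + 1L
  do.call(cbind, lapply(0:(k - 1L), function(o) {
    X[(1L + o):(Tk + o), , drop = FALSE]
  }))
}

# X: T x d_in matrix of (frozen or upstream) token vectors.
# valid_len: number of non-pad rows; windows touching padding are masked out
# of the max-pool (equivalent to setting them to -Inf).
cnn_head_forward <- function(p, hp, X, valid_len = nrow(X),
                             dropout_p = 0, drop_mask = NULL) {
  kmax <- max(hp$kernel_sizes)
  if (nrow(X) < kmax) {
    warning("input length ", nrow(X), " < largest kernel ", kmax,
            "; padding up with zero vectors", call. = FALSE)
    X <- rbind(X, matrix(0, kmax - nrow(X), ncol(X)))
  }
  pooled <- numeric(hp$pooled_dim)
  conv_maps <- list()
  caches <- list()
  pos <- 0L
  for (k in hp$kernel_sizes) {
    C <- im2col(X, k)
    Z <- add_bias(C %*% p[[paste0("convW", k)]], p[[paste0("convb", k)]])
    Zr <- pmax(Z, 0)
    vk <- max(valid_len - k + 1L, 1L)
    vk <- min(vk, nrow(Zr))
    arg <- integer(hp$filters)
    for (f in seq_len(hp$filters)) {
      arg[f] <- which.max(Zr[seq_len(vk), f])
      pooled[pos + f] <- Zr[arg[f], f]
    }
    conv_maps[[as.character(k)]] <- Z
    caches[[as.character(k)]] <- list(C = C, Z = Z, arg = arg, vk = vk)
    pos <- pos + hp$filters
  }
  if (dropout_p > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- (stats::runif(hp$pooled_dim) >= dropout_p) /
        (1 - dropout_p)
    }
    pooled_d <- pooled * drop_mask
  } else {
    drop_mask <- rep(1, hp$pooled_dim)
    pooled_d <- pooled
  }
  logits <- drop(pooled_d %*% p$W_out) + p$b_out
  list(logits = logits, pooled = pooled, conv_maps = conv_maps,
       cache = list(caches = caches, pooled_d = pooled_d,
                    drop_mask = drop_mask, T_in = nrow(X)))
}

cnn_head_backward <- function(p, hp, fwd, dlogits, need_dX = FALSE) {
  g <- list()
  g$W_out <- outer(fwd$cache$pooled_d, dlogits)
  g$b_out <- dlogits
  dpooled <- drop(p$W_out %*% dlogits) * fwd$cache$drop_mask
  dX <- if (need_dX) matrix(0, fwd$cache$T_in, hp$d_in) else NULL
  pos <- 0L
  for (k in hp$kernel_sizes) {
    cc <- fwd$cache$caches[[as.character(k)]]
    dZ <- matrix(0, nrow(cc$Z), hp$filters)
    for (f in seq_len(hp$filters)) {
      a <- cc$arg[f]
      if (cc$Z[a, f] > 0) dZ[a, f] <- dpooled[pos + f]
    }
    g[[paste0("convW", k)]] <- crossprod(cc$C, dZ)
    g[[paste0("convb", k)]] <- colSums(dZ)
    if (need_dX) {
      dC <- tcrossprod(dZ, p[[paste0("convW", k)]])
      active <- which(rowSums(dZ != 0) > 0)
      for (a in active) {
        # unfold the im2col row back onto the k input rows it covers
        for (o in 0:(k - 1L)) {
          cols <- (o * hp$d_in + 1L):((o + 1L) * hp$d_in)
          dX[a + o, ] <- dX[a + o, ] + dC[a, cols]
        }
      }
    }
    pos <- pos + hp$filters
  }
  list(grads = g, dX = dX)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# accumulate a (possibly weighted) gradient list into an environment
acc_grads <- function(env, grads, weight = 1) {
  for (nm in names(grads)) {
    cur <- env[[nm]]
    env[[nm]] <- if (is.null(cur)) weight * grads[[nm]]
    else cur + weight * grads[[nm]]
  }
  invisible(env)
}
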