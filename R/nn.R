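## Neural-network primitives, written directly in base R on top of BLAS
## matrix products.  Feature maps are stored as (B*T) x C matrices with
## sample-major rows (all T positions of sample 1, then sample 2, ...);
## every *_fwd returns the output plus a cache consumed by the matching
## *_bwd, which returns input gradients and parameter gradients.

glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

add_bias <- function(M, b) add_bias_cpp(M, b)

relu_fwd <- function(X) pmax(X, 0)
relu_bwd <- function(dY, X) dY * (X > 0)

row_softmax <- function(S) {
  ## stable row softmax; -Inf entries become exact zeros
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

## ---- position-wise dense -------------------------------------------------

dense_fwd <- function(X, W, b) add_bias(X %*% W, b)
dense_bwd <- function(dY, X, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

## ---- 1-D convolution ('same' padding, stride 1) ---------------------------
##
## Y[t, ] = b + sum_j X[t + j - left, ] %*% W_j within each sample, rows
## outside the sample contributing zero.  W holds k stacked (Cin x Cout)
## tap blocks (im2col weight layout).  The row-shifted GEMM accumulation
## is the hottest loop in the package and lives in src/conv_ops.cpp.

conv_fwd <- function(X, W, b, k, B, T) {
  list(Y = conv1d_fwd_cpp(X, W, b, k, B, T))
}

conv_bwd <- function(dY, X, W, k, B, T) {
  r <- conv1d_bwd_cpp(dY, X, W, k, B, T)
  r$db <- as.vector(r$db)
  r
}

## ---- Conv -> ReLU -> Conv -> ReLU -> Conv branch --------------------------

branch_fwd <- function(X, prm, kernels, B, T) {
  c1 <- conv_fwd(X, prm$conv1$W, prm$conv1$b, kernels[1], B, T)
  A1 <- relu_fwd(c1$Y)
  c2 <- conv_fwd(A1, prm$conv2$W, prm$conv2$b, kernels[2], B, T)
  A2 <- relu_fwd(c2$Y)
  c3 <- conv_fwd(A2, prm$conv3$W, prm$conv3$b, kernels[3], B, T)
  list(Y = c3$Y,
       cache = list(X = X, Z1 = c1$Y, A1 = A1, Z2 = c2$Y, A2 = A2,
                    B = B, T = T))
}

branch_bwd <- function(dY, cache, prm, kernels) {
  B <- cache$B; T <- cache$T
  b3 <- conv_bwd(dY, cache$A2, prm$conv3$W, kernels[3], B, T)
  dA2 <- relu_bwd(b3$dX, cache$Z2)
  b2 <- conv_bwd(dA2, cache$A1, prm$conv2$W, kernels[2], B, T)
  dA1 <- relu_bwd(b2$dX, cache$Z1)
  b1 <- conv_bwd(dA1, cache$X, prm$conv1$W, kernels[1], B, T)
  list(dX = b1$dX,
       grads = list(conv1 = list(W = b1$dW, b = b1$db),
                    conv2 = list(W = b2$dW, b = b2$db),
                    conv3 = list(W = b3$dW, b = b3$db)))
}

## ---- embeddings ----------------------------------------------------------

## tok: integer matrix (B x T), 0-based indices; returns (B*T) x E
embed_fwd <- function(tok, table) {
  ids <- as.vector(t(tok)) + 1L
  list(Y = table[ids, , drop = FALSE], ids = ids)
}

embed_bwd <- function(dY, ids, vocab_size, E) {
  g <- rowsum(dY, group = ids)
  dT <- matrix(0, vocab_size, E)
  dT[as.integer(rownames(g)), ] <- g
  dT
}

## ---- sinusoidal positional encoding --------------------------------------

positional_encoding <- function(T, d) {
  pos <- matrix(seq_len(T) - 1L, T, d)
  i2 <- matrix(rep(0:(d - 1L) %/% 2L * 2L, each = T), T, d)
  ang <- pos / 10000^(i2 / d)
  even <- (col(ang) %% 2L) == 1L  # columns 1,3,... hold sin (0-based even dims)
  out <- matrix(0, T, d)
  out[even] <- sin(ang[even])
  out[!even] <- cos(ang[!even])
  out
}

## ---- layer norm (per position, over channels) -----------------------------

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  Xhat <- xc * inv
  list(Y = add_bias(Xhat * rep(g, each = nrow(X)), b), Xhat = Xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  Xhat <- cache$Xhat
  dXhat <- dY * rep(g, each = nrow(dY))
  dX <- cache$inv * (dXhat - rowMeans(dXhat) - Xhat * rowMeans(dXhat * Xhat))
  list(dX = dX, dg = colSums(dY * Xhat), db = colSums(dY))
}

## ---- scaled dot-product attention (one head, one sample) ------------------

attn_core_fwd <- function(Q, K, V, keymask = NULL) {
  dk <- ncol(K)
  S <- tcrossprod(Q, K) / sqrt(dk)
  if (!is.null(keymask)) {
    if (all(keymask == 0)) stop2("attention is undefined with every key masked")
    S[, keymask == 0] <- -Inf
  }
  A <- row_softmax(S)
  list(Y = A %*% V, A = A)
}

attn_core_bwd <- function(dY, A, Q, K, V) {
  dk <- ncol(K)
  dA <- tcrossprod(dY, V)
  dV <- crossprod(A, dY)
  dS <- A * (dA - rowSums(dA * A))     # masked columns have A = 0, hence dS = 0
  list(dQ = (dS %*% K) / sqrt(dk),
       dK = (crossprod(dS, Q)) / sqrt(dk),
       dV = dV)
}

## ---- multi-head self-attention over a batch -------------------------------

mha_fwd <- function(X, p, n_heads, B, T, keymask) {
  d <- ncol(X)
  dh <- d %/% n_heads
  Q <- dense_fwd(X, p$Wq, p$bq)
  K <- dense_fwd(X, p$Wk, p$bk)
  V <- dense_fwd(X, p$Wv, p$bv)
  O <- matrix(0, nrow(X), d)
  Acache <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    km <- keymask[b, ]
    Ah <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      a <- attn_core_fwd(Q[rows, hc, drop = FALSE], K[rows, hc, drop = FALSE],
                         V[rows, hc, drop = FALSE], km)
      O[rows, hc] <- a$Y
      Ah[[h]] <- a$A
    }
    Acache[[b]] <- Ah
  }
  Y <- dense_fwd(O, p$Wo, p$bo)
  list(Y = Y, Q = Q, K = K, V = V, O = O, A = Acache)
}

mha_bwd <- function(dY, cache, X, p, n_heads, B, T) {
  d <- ncol(X)
  dh <- d %/% n_heads
  g_o <- dense_bwd(dY, cache$O, p$Wo)
  dO <- g_o$dX
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    for (h in seq_len(n_heads)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      gb <- attn_core_bwd(dO[rows, hc, drop = FALSE], cache$A[[b]][[h]],
                          cache$Q[rows, hc, drop = FALSE],
                          cache$K[rows, hc, drop = FALSE],
                          cache$V[rows, hc, drop = FALSE])
      dQ[rows, hc] <- gb$dQ; dK[rows, hc] <- gb$dK; dV[rows, hc] <- gb$dV
    }
  }
  g_q <- dense_bwd(dQ, X, p$Wq)
  g_k <- dense_bwd(dK, X, p$Wk)
  g_v <- dense_bwd(dV, X, p$Wv)
  list(dX = g_q$dX + g_k$dX + g_v$dX,
       grads = list(Wq = g_q$dW, bq = g_q$db, Wk = g_k$dW, bk = g_k$db,
                    Wv = g_v$dW, bv = g_v$db, Wo = g_o$dW, bo = g_o$db))
}

## ---- transformer encoder layer (post-norm) --------------------------------

tf_layer_fwd <- function(X, p, n_heads, B, T, keymask) {
  mh <- mha_fwd(X, p, n_heads, B, T, keymask)
  R1 <- X + mh$Y
  l1 <- ln_fwd(R1, p$g1, p$nb1)
  Z1 <- dense_fwd(l1$Y, p$W1, p$fb1)
  A1 <- relu_fwd(Z1)
  Z2 <- dense_fwd(A1, p$W2, p$fb2)
  R2 <- l1$Y + Z2
  l2 <- ln_fwd(R2, p$g2, p$nb2)
  list(Y = l2$Y,
       cache = list(X = X, mh = mh, l1 = l1, L1Y = l1$Y, Z1 = Z1, A1 = A1,
                    l2 = l2))
}

tf_layer_bwd <- function(dY, cache, p, n_heads, B, T) {
  g_l2 <- ln_bwd(dY, cache$l2, p$g2)
  dR2 <- g_l2$dX
  g_2 <- dense_bwd(dR2, cache$A1, p$W2)
  dA1 <- relu_bwd(g_2$dX, cache$Z1)
  g_1 <- dense_bwd(dA1, cache$L1Y, p$W1)
  dL1Y <- dR2 + g_1$dX
  g_l1 <- ln_bwd(dL1Y, cache$l1, p$g1)
  dR1 <- g_l1$dX
  g_mh <- mha_bwd(dR1, cache$mh, cache$X, p, n_heads, B, T)
  list(dX = dR1 + g_mh$dX,
       grads = c(g_mh$grads,
                 list(g1 = g_l1$dg, nb1 = g_l1$db,
                      W1 = g_1$dW, fb1 = g_1$db, W2 = g_2$dW, fb2 = g_2$db,
                      g2 = g_l2$dg, nb2 = g_l2$db)))
}

## ---- adaptive mean pooling along time -------------------------------------

pool_matrix <- function(T, bins) {
  P <- matrix(0, bins, T)
  for (i in seq_len(bins)) {
    s <- floor((i - 1) * T / bins) + 1L
    e <- ceiling(i * T / bins)
    P[i, s:e] <- 1 / (e - s + 1L)
  }
  P
}

pool_fwd <- function(X, P, B, T) {
  bins <- nrow(P)
  Y <- matrix(0, B * bins, ncol(X))
  for (b in seq_len(B)) {
    Y[((b - 1L) * bins + 1L):(b * bins), ] <-
      P %*% X[((b - 1L) * T + 1L):(b * T), , drop = FALSE]
  }
  Y
}

pool_bwd <- function(dY, P, B, T) {
  bins <- nrow(P)
  dX <- matrix(0, B * T, ncol(dY))
  tP <- t(P)
  for (b in seq_len(B)) {
    dX[((b - 1L) * T + 1L):(b * T), ] <-
      tP %*% dY[((b - 1L) * bins + 1L):(b * bins), , drop = FALSE]
  }
  dX
}

## ---- global max pooling along time ----------------------------------------

gmax_fwd <- function(X, B, T) {
  C <- ncol(X)
  Y <- matrix(0, B, C)
  idx <- matrix(0L, B, C)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    Xb <- X[rows, , drop = FALSE]
    am <- max.col(t(Xb), ties.method = "first")
    idx[b, ] <- rows[am]
    Y[b, ] <- Xb[cbind(am, seq_len(C))]
  }
  list(Y = Y, idx = idx)
}

gmax_bwd <- function(dY, idx, n_rows) {
  C <- ncol(dY)
  dX <- matrix(0, n_rows, C)
  for (j in seq_len(C)) {
    dX[cbind(idx[, j], j)] <- dX[cbind(idx[, j], j)] + dY[, j]
  }
  dX
}

## ---- per-sample time mean --------------------------------------------------

tmean_fwd <- function(X, B, T) {
  rowsum(X, group = rep(seq_len(B), each = T), reorder = FALSE) / T
}

tmean_bwd <- function(dI, B, T) dI[rep(seq_len(B), each = T), , drop = FALSE] / T

## ---- selective fusion (channel-softmax competition) ------------------------

## L, G: (B*T) x C streams; gates computed per sample from the time mean of
## X = [L ; G], one softmax pair per channel.
sfm_fwd <- function(L, G, p, B, T) {
  X <- cbind(L, G)
  I <- tmean_fwd(X, B, T)                       # B x 2C
  Zf <- dense_fwd(I, p$Wf, p$bf)
  H <- relu_fwd(Zf)                             # B x d_r
  X1 <- dense_fwd(H, p$Wu1, p$bu1)              # B x C
  X2 <- dense_fwd(H, p$Wu2, p$bu2)
  sL <- 1 / (1 + exp(X2 - X1))                  # pairwise softmax
  sG <- 1 - sL
  rep_idx <- rep(seq_len(B), each = T)
  Y <- cbind(L * sL[rep_idx, , drop = FALSE], G * sG[rep_idx, , drop = FALSE])
  list(Y = Y, cache = list(L = L, G = G, I = I, Zf = Zf, H = H,
                           sL = sL, sG = sG, rep_idx = rep_idx))
}

sfm_bwd <- function(dY, cache, p, B, T) {
  C <- ncol(cache$L)
  dY1 <- dY[, seq_len(C), drop = FALSE]
  dY2 <- dY[, C + seq_len(C), drop = FALSE]
  ri <- cache$rep_idx
  dL <- dY1 * cache$sL[ri, , drop = FALSE]
  dG <- dY2 * cache$sG[ri, , drop = FALSE]
  dsL <- rowsum(dY1 * cache$L, group = ri, reorder = FALSE)
  dsG <- rowsum(dY2 * cache$G, group = ri, reorder = FALSE)
  dDiff <- (dsL - dsG) * cache$sL * cache$sG    # d/d(X1 - X2)
  g1 <- dense_bwd(dDiff, cache$H, p$Wu1)
  g2 <- dense_bwd(-dDiff, cache$H, p$Wu2)
  dH <- g1$dX + g2$dX
  dZf <- relu_bwd(dH, cache$Zf)
  gf <- dense_bwd(dZf, cache$I, p$Wf)
  dX <- tmean_bwd(gf$dX, B, T)
  dL <- dL + dX[, seq_len(C), drop = FALSE]
  dG <- dG + dX[, C + seq_len(C), drop = FALSE]
  list(dL = dL, dG = dG,
       grads = list(Wf = gf$dW, bf = gf$db, Wu1 = g1$dW, bu1 = g1$db,
                    Wu2 = g2$dW, bu2 = g2$db))
}

## ---- squeeze-and-excitation gating -----------------------------------------

se_fwd <- function(X, p, B, T) {
  s <- tmean_fwd(X, B, T)                       # B x C
  Z1 <- dense_fwd(s, p$W1, p$b1)
  H <- relu_fwd(Z1)
  Z2 <- dense_fwd(H, p$W2, p$b2)
  E <- 1 / (1 + exp(-Z2))                       # gates in (0, 1)
  ri <- rep(seq_len(B), each = T)
  list(Y = X * E[ri, , drop = FALSE],
       cache = list(X = X, s = s, Z1 = Z1, H = H, E = E, ri = ri))
}

se_bwd <- function(dY, cache, p, B, T) {
  dX <- dY * cache$E[cache$ri, , drop = FALSE]
  dE <- rowsum(dY * cache$X, group = cache$ri, reorder = FALSE)
  dZ2 <- dE * cache$E * (1 - cache$E)
  g2 <- dense_bwd(dZ2, cache$H, p$W2)
  dZ1 <- relu_bwd(g2$dX, cache$Z1)
  g1 <- dense_bwd(dZ1, cache$s, p$W1)
  dX <- dX + tmean_bwd(g1$dX, B, T)
  list(dX = dX, grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db))
}

## ---- biased feature interaction --------------------------------------------

bfim_fwd <- function(Ad, At, p, variant = "affine") {
  if (variant == "bilinear") {
    P1 <- dense_fwd(Ad, p$W1, p$b1)
    P2 <- dense_fwd(At, p$W2, p$b2)
    Z <- P1 * P2
    Y <- relu_fwd(add_bias(Z, p$b))
    list(Y = Y, cache = list(Ad = Ad, At = At, P1 = P1, P2 = P2, Z = Z))
  } else {
    Xc <- cbind(Ad, At, Ad * At)
    Z <- dense_fwd(Xc, p$W, p$b)
    list(Y = relu_fwd(Z), cache = list(Ad = Ad, At = At, Xc = Xc, Z = Z))
  }
}

bfim_bwd <- function(dY, cache, p, variant = "affine") {
  if (variant == "bilinear") {
    dZb <- relu_bwd(dY, add_bias(cache$Z, p$b))
    dP1 <- dZb * cache$P2
    dP2 <- dZb * cache$P1
    g1 <- dense_bwd(dP1, cache$Ad, p$W1)
    g2 <- dense_bwd(dP2, cache$At, p$W2)
    list(dAd = g1$dX, dAt = g2$dX,
         grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
                      b = colSums(dZb)))
  } else {
    C <- ncol(cache$Ad)
    dZ <- relu_bwd(dY, cache$Z)
    g <- dense_bwd(dZ, cache$Xc, p$W)
    dXc <- g$dX
    dAd <- dXc[, seq_len(C), drop = FALSE] +
      dXc[, 2L * C + seq_len(C), drop = FALSE] * cache$At
    dAt <- dXc[, C + seq_len(C), drop = FALSE] +
      dXc[, 2L * C + seq_len(C), drop = FALSE] * cache$Ad
    list(dAd = dAd, dAt = dAt, grads = list(W = g$dW, b = g$db))
  }
}

## ---- shared cross attention -------------------------------------------------

## One shared (Wq, Wk, Wv) projection triple serves both directions; the
## attention output is added to the residual stream on each side.
cross_fwd <- function(D, Tt, p, B, T) {
  Qd <- dense_fwd(D, p$Wq, p$bq); Kd <- dense_fwd(D, p$Wk, p$bk)
  Vd <- dense_fwd(D, p$Wv, p$bv)
  Qt <- dense_fwd(Tt, p$Wq, p$bq); Kt <- dense_fwd(Tt, p$Wk, p$bk)
  Vt <- dense_fwd(Tt, p$Wv, p$bv)
  Ad <- matrix(0, nrow(D), ncol(D)); At <- Ad
  Wd <- vector("list", B); Wt <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    a1 <- attn_core_fwd(Qd[rows, , drop = FALSE], Kt[rows, , drop = FALSE],
                        Vt[rows, , drop = FALSE])
    a2 <- attn_core_fwd(Qt[rows, , drop = FALSE], Kd[rows, , drop = FALSE],
                        Vd[rows, , drop = FALSE])
    Ad[rows, ] <- a1$Y; At[rows, ] <- a2$Y
    Wd[[b]] <- a1$A; Wt[[b]] <- a2$A
  }
  list(Ad = D + Ad, At = Tt + At,
       cache = list(D = D, Tt = Tt, Qd = Qd, Kd = Kd, Vd = Vd,
                    Qt = Qt, Kt = Kt, Vt = Vt, Wd = Wd, Wt = Wt))
}

cross_bwd <- function(dAd, dAt, cache, p, B, T) {
  dQd <- matrix(0, nrow(dAd), ncol(dAd)); dKd <- dQd; dVd <- dQd
  dQt <- dQd; dKt <- dQd; dVt <- dQd
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    g1 <- attn_core_bwd(dAd[rows, , drop = FALSE], cache$Wd[[b]],
                        cache$Qd[rows, , drop = FALSE],
                        cache$Kt[rows, , drop = FALSE],
                        cache$Vt[rows, , drop = FALSE])
    g2 <- attn_core_bwd(dAt[rows, , drop = FALSE], cache$Wt[[b]],
                        cache$Qt[rows, , drop = FALSE],
                        cache$Kd[rows, , drop = FALSE],
                        cache$Vd[rows, , drop = FALSE])
    dQd[rows, ] <- g1$dQ; dKt[rows, ] <- g1$dK; dVt[rows, ] <- g1$dV
    dQt[rows, ] <- g2$dQ; dKd[rows, ] <- g2$dK; dVd[rows, ] <- g2$dV
  }
  gq1 <- dense_bwd(dQd, cache$D, p$Wq);  gq2 <- dense_bwd(dQt, cache$Tt, p$Wq)
  gk1 <- dense_bwd(dKd, cache$D, p$Wk);  gk2 <- dense_bwd(dKt, cache$Tt, p$Wk)
  gv1 <- dense_bwd(dVd, cache$D, p$Wv);  gv2 <- dense_bwd(dVt, cache$Tt, p$Wv)
  list(dD = dAd + gq1$dX + gk1$dX + gv1$dX,
       dTt = dAt + gq2$dX + gk2$dX + gv2$dX,
       grads = list(Wq = gq1$dW + gq2$dW, bq = gq1$db + gq2$db,
                    Wk = gk1$dW + gk2$dW, bk = gk1$db + gk2$db,
                    Wv = gv1$dW + gv2$dW, bv = gv1$db + gv2$db))
}

## ---- dropout ----------------------------------------------------------------

dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- (stats::runif(length(X)) >= rate) / (1 - rate)
  dim(mask) <- dim(X)
  list(Y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

## ---- Adam -------------------------------------------------------------------

## params/grads are nested lists with numeric leaves; state mirrors them.
adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

## accumulate two grad trees (a may be NULL)
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (nm in names(b)) a[[nm]] <- grad_add(a[[nm]], b[[nm]])
    a
  } else a + b
}
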