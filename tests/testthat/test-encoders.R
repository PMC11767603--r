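test_that("embedding lookup propagates pad rows and masks", {
  v <- build_smiles_vocabulary(c("CO"))
  table <- matrix(rnorm(3 * 4), 3, 4)
  all_pad <- tokenize_chars("", v, max_len = 5L)
  E <- embed_tokens(all_pad, table)
  for (t in 1:5) expect_equal(E[t, ], table[1, ])

  ## one-hot identity table: row t is the one-hot of token t
  tk <- tokenize_chars("CO", v, max_len = 3L)
  I <- diag(3)
  Eh <- embed_tokens(tk, I)
  expect_equal(Eh[1, ], I[tk$indices[1] + 1L, ])
  expect_equal(Eh[2, ], I[tk$indices[2] + 1L, ])
  expect_false(identical(Eh[1, ], Eh[2, ]))
  expect_equal(attr(Eh, "mask"), tk$mask)

  bad <- tk; bad$indices[1] <- 99L
  expect_error(embed_tokens(bad, table), "out of range")
})

test_that("conv branch matches a scalar affine/ReLU chain at kernel width 1", {
  p <- conv_branch_params(1L, channels = c(1L, 1L, 1L), kernels = c(1L, 1L, 1L))
  w <- c(0.7, -1.3, 2.1); b <- c(0.2, 0.4, -0.1)
  for (i in 1:3) {
    p[[paste0("conv", i)]]$W <- matrix(w[i])
    p[[paste0("conv", i)]]$b <- b[i]
  }
  for (v in c(-2, -0.1, 0, 0.3, 1.5)) {
    manual <- w[3] * max(w[2] * max(w[1] * v + b[1], 0) + b[2], 0) + b[3]
    expect_equal(conv_branch(matrix(v), p)[1, 1], manual, tolerance = 1e-12)
  }
})

test_that("conv branch is zero-preserving and uses the declared channels", {
  p <- conv_branch_params(4L, channels = c(3L, 4L, 5L), kernels = c(2L, 3L, 3L))
  Y <- conv_branch(matrix(0, 6, 4), p)
  expect_equal(dim(Y), c(6L, 5L))
  expect_true(all(Y == 0))

  ## reference defaults give 96 output channels
  pd <- conv_branch_params(8L)
  expect_equal(ncol(conv_branch(matrix(rnorm(10 * 8), 10, 8), pd)), 96L)

  expect_error(conv_branch(matrix(0, 6, 3), p), "channels")
})

test_that("the compiled convolution agrees with a direct im2col reference", {
  set.seed(6)
  for (i in 1:12) {
    T <- sample(3:9, 1); Cin <- sample(1:4, 1); Cout <- sample(1:4, 1)
    k <- sample(1:5, 1)
    X <- matrix(rnorm(T * Cin), T, Cin)
    W <- matrix(rnorm(k * Cin * Cout), k * Cin, Cout)
    b <- rnorm(Cout)
    Y <- mcfdti:::conv_fwd(X, W, b, k, B = 1L, T = T)$Y
    expect_equal(Y, conv_reference(X, W, b, k), tolerance = 1e-12)
  }
  ## batched call equals per-sample calls
  T <- 5L; Cin <- 3L; k <- 3L
  X1 <- matrix(rnorm(T * Cin), T, Cin); X2 <- matrix(rnorm(T * Cin), T, Cin)
  W <- matrix(rnorm(k * Cin * 2), k * Cin, 2); b <- rnorm(2)
  YB <- mcfdti:::conv_fwd(rbind(X1, X2), W, b, k, B = 2L, T = T)$Y
  expect_equal(YB[1:T, ], mcfdti:::conv_fwd(X1, W, b, k, 1L, T)$Y)
  expect_equal(YB[T + 1:T, ], mcfdti:::conv_fwd(X2, W, b, k, 1L, T)$Y)
})

test_that("drug encoding concatenates the two branch outputs", {
  v <- build_smiles_vocabulary(c("CCO", "C=N"))
  table <- matrix(rnorm(v$size * 4), v$size, 4)
  b1 <- conv_branch_params(4L, c(2L, 3L, 4L), c(2L, 3L, 3L), seed = 1L)
  b2 <- conv_branch_params(4L, c(2L, 3L, 4L), c(2L, 3L, 3L), seed = 2L)
  tk <- tokenize_chars("C=O", v, max_len = 6L)
  Fd <- encode_drug(tk, table, b1, b2)
  expect_equal(dim(Fd), c(6L, 8L))

  ## tied branches give two identical halves
  Ft <- encode_drug(tk, table, b1, b1)
  expect_equal(Ft[, 1:4], Ft[, 5:8])

  ## zero embedding, zero biases: zero output
  F0 <- encode_drug(tk, table * 0, b1, b2)
  expect_true(all(F0 == 0))
})

test_that("scaled dot-product attention normalizes over unmasked keys", {
  V <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  ## zero queries: uniform softmax, rows equal the value mean
  Y <- scaled_dot_attention(matrix(0, 2, 4), matrix(rnorm(12), 3, 4), V)
  expect_equal(Y[1, ], colMeans(V))
  expect_equal(Y[2, ], colMeans(V))

  ## a single unmasked key passes its value through exactly
  Y1 <- scaled_dot_attention(matrix(rnorm(4), 1, 4),
                             matrix(rnorm(12), 3, 4), V,
                             mask = c(0, 1, 0))
  expect_equal(drop(Y1), V[2, ], ignore_attr = TRUE)

  ## hand-evaluated softmax, d_k = 1: weights (e^2, 1)/(e^2 + 1)
  Y2 <- scaled_dot_attention(matrix(2), matrix(c(1, 0)), matrix(c(1, 0)))
  expect_equal(drop(Y2), exp(2) / (exp(2) + 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  w <- attr(scaled_dot_attention(matrix(rnorm(8), 2, 4),
                                 matrix(rnorm(16), 4, 4),
                                 matrix(rnorm(8), 4, 2),
                                 mask = c(1, 1, 0, 1)), "weights")
  expect_equal(rowSums(w), c(1, 1), tolerance = 1e-9)
  expect_true(all(w[, 3] == 0))

  expect_error(scaled_dot_attention(matrix(1), matrix(c(1, 2)),
                                    matrix(c(1, 2)), mask = c(0, 0)),
               "every key masked")
})

test_that("the transformer path respects masks and the zero-layer identity", {
  m <- train_bpe(c("MKLVAG", "MKWWAG"), 2L)
  tk <- encode_bpe("MKLVAG", m, max_tokens = 8L)

  p0 <- transformer_params(m$vocab$size, d_model = 6L, n_heads = 2L,
                           n_layers = 0L, ffn_dim = 8L, seed = 3L)
  G0 <- encode_target_transformer(tk, p0)
  manual <- p0$embed[tk$indices + 1L, ] + mcfdti:::positional_encoding(8L, 6L)
  expect_equal(unname(G0[, ]), unname(manual), ignore_attr = TRUE)

  p2 <- transformer_params(m$vocab$size, d_model = 8L, n_heads = 2L,
                           n_layers = 2L, ffn_dim = 12L, seed = 4L)
  G <- encode_target_transformer(tk, p2)
  expect_equal(dim(G), c(8L, 8L))
  expect_true(all(is.finite(G)))

  ## changing token values at masked positions leaves unmasked rows alone
  tk2 <- tk
  pad_pos <- which(tk$mask == 0L)
  tk2$indices[pad_pos] <- (tk2$indices[pad_pos] + 1L) %% m$vocab$size
  G2 <- encode_target_transformer(tk2, p2)
  live <- which(tk$mask == 1L)
  expect_equal(G[live, ], G2[live, ], tolerance = 1e-6)

  empty <- encode_bpe("", m, max_tokens = 4L)
  expect_error(encode_target_transformer(empty, p2), "all-masked")
})

test_that("the two-path target encoder aligns and concatenates", {
  m <- train_bpe(c("MKLVAGGW", "MKWWAGYY"), 2L)
  pv <- amino_acid_vocabulary()
  prm <- target_encoder_params(pv$size, m$vocab$size, embed_dim = 4L,
                               channels = c(3L, 4L, 5L), kernels = c(2L, 3L, 3L),
                               d_model = 6L, n_heads = 2L, n_layers = 1L,
                               ffn_dim = 8L, proj_channels = 4L,
                               pool_bins = 3L, seed = 9L)
  tk_c <- tokenize_chars("MKLVAGGW", pv, 10L, allowed = mcfdti:::AA_LETTERS)
  tk_b <- encode_bpe("MKLVAGGW", m, 8L)
  enc <- encode_target(tk_c, tk_b, prm)
  expect_equal(dim(enc$L), c(10L, 5L))
  expect_equal(dim(enc$G), c(8L, 6L))
  expect_equal(dim(enc$F_target), c(3L, 8L))

  ## zero weights everywhere gives a zero fused map
  prm0 <- prm
  prm0$char_embed <- prm0$char_embed * 0
  prm0$tf$embed <- prm0$tf$embed * 0
  for (l in seq_along(prm0$tf$layers)) {
    prm0$tf$layers[[l]] <- lapply(prm0$tf$layers[[l]], function(x) x * 0)
  }
  prm0$proj_L$W <- prm0$proj_L$W * 0
  prm0$proj_G$W <- prm0$proj_G$W * 0
  enc0 <- encode_target(tk_c, tk_b, prm0)
  expect_true(all(enc0$F_target == 0))
})
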