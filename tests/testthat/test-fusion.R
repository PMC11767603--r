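test_that("shared cross attention is symmetric and normalized", {
  C <- 4L
  prm <- cross_attention_params(C, seed = 2L)
  Fmap <- matrix(rnorm(5 * C), 5, C)
  out <- shared_cross_attention(Fmap, Fmap, prm)
  ## identical inputs with shared projections: both directions agree
  expect_equal(out$A_d, out$A_t, tolerance = 1e-12)

  ## a single-position drug map is a degenerate softmax: every target row
  ## receives exactly that drug position's value projection (plus residual)
  d1 <- matrix(rnorm(C), 1, C)
  tgt <- matrix(rnorm(6 * C), 6, C)
  out2 <- shared_cross_attention(d1, tgt, prm)
  vproj <- drop(d1 %*% prm$Wv + prm$bv)
  for (r in 1:6) expect_equal(out2$A_t[r, ] - tgt[r, ], vproj,
                              tolerance = 1e-9)

  expect_error(shared_cross_attention(matrix(0, 2, 3), matrix(0, 2, 4), prm),
               "channel width")
})

test_that("BFIM computes the biased interaction position-wise", {
  C <- 1L
  prm <- bfim_params(C, seed = 1L)
  ## zero inputs, zero bias: zero output
  prm0 <- prm; prm0$W <- prm0$W * 0
  expect_true(all(bfim(matrix(0, 3, 1), matrix(0, 3, 1), prm0) == 0))

  ## zero weights with bias b: every position outputs ReLU(b)
  prm0$b <- c(0.3, -0.2)
  Y <- bfim(matrix(rnorm(4), 4, 1), matrix(rnorm(4), 4, 1), prm0)
  for (r in 1:4) expect_equal(Y[r, ], pmax(c(0.3, -0.2), 0))

  ## scalar toy: unit weights, A_d = 2, A_t = 3 gives w . [2, 3, 6] + b
  prm1 <- prm
  prm1$W <- matrix(1, 3, 2)
  prm1$b <- c(0.5, -20)
  Y1 <- bfim(matrix(2), matrix(3), prm1)
  expect_equal(Y1[1, ], c(2 + 3 + 6 + 0.5, 0))

  expect_error(bfim(matrix(0, 2, 1), matrix(0, 3, 1), prm), "identical shapes")
})

test_that("SFM gates form a per-channel softmax pair", {
  C <- 3L
  prm <- sfm_params(C, r = 4L, seed = 6L)
  L <- matrix(rnorm(4 * C), 4, C); G <- matrix(rnorm(4 * C), 4, C)

  Xf <- sfm(L, G, prm)
  gates <- attr(Xf, "gates")
  expect_equal(gates$s_L + gates$s_G, rep(1, C), tolerance = 1e-9)
  expect_equal(Xf[, 1:C], L * rep(gates$s_L, each = 4), tolerance = 1e-12)

  ## tied expansion maps: both gates are exactly one half
  tied <- prm; tied$Wu2 <- tied$Wu1; tied$bu2 <- tied$bu1
  Xf2 <- sfm(L, G, tied)
  expect_equal(Xf2, 0.5 * cbind(L, G), ignore_attr = TRUE)

  expect_error(sfm(L[0, , drop = FALSE], G[0, , drop = FALSE], prm), "T = 0")
})

test_that("a hand-built SFM reproduces the scalar softmax pair", {
  prm <- sfm_params(1L, r = 4L, seed = 1L)   # d_r = 4
  ## force X1 = 1, X2 = 0 irrespective of the input
  prm$Wf <- matrix(0, 2, 4); prm$bf <- c(1, 0, 0, 0)
  prm$Wu1 <- matrix(c(1, 0, 0, 0), 4, 1); prm$bu1 <- 0
  prm$Wu2 <- matrix(0, 4, 1); prm$bu2 <- 0
  L <- matrix(2); G <- matrix(5)
  Xf <- sfm(L, G, prm)
  sL <- exp(1) / (exp(1) + 1)            # about 0.7311
  expect_equal(attr(Xf, "gates")$s_L, sL, tolerance = 1e-12)
  expect_equal(Xf[1, ], c(2 * sL, 5 * (1 - sL)), tolerance = 1e-12)
})

test_that("SE recalibration gates lie in (0,1) and default to one half", {
  prm <- sfm_params(2L, seed = 3L)
  X <- matrix(rnorm(5 * 4), 5, 4)

  z <- prm
  z$se$W1 <- z$se$W1 * 0; z$se$W2 <- z$se$W2 * 0
  Y <- se_recalibrate(X, z)
  expect_equal(Y, 0.5 * X, ignore_attr = TRUE)

  g <- attr(se_recalibrate(X, prm), "gates")
  expect_true(all(g > 0 & g < 1))
})

test_that("the prediction head emits calibrated probabilities", {
  hp <- head_params(3L, widths = c(4L), seed = 5L)
  z <- hp
  for (i in seq_along(z$layers)) z$layers[[i]]$W <- z$layers[[i]]$W * 0
  ## all-zero parameters: sigmoid(0) = 0.5
  expect_equal(predict_interaction(matrix(rnorm(6), 3, 2),
                                   matrix(rnorm(4), 4, 1), z), 0.5)

  set.seed(8)
  for (i in 1:20) {
    p <- predict_interaction(matrix(rnorm(6) * 10, 3, 2),
                             matrix(rnorm(4) * 10, 4, 1), hp)
    expect_true(p >= 0 && p <= 1)
  }

  ## two-feature toy with explicit weights: hand-computed sigmoid
  h2 <- head_params(2L, widths = integer(0), seed = 1L)
  h2$layers[[1]]$W <- matrix(c(1, -1), 2, 1)
  h2$layers[[1]]$b <- 0.5
  a <- 1.2; b <- 0.4
  p <- predict_interaction(matrix(c(a, -1), 2, 1), matrix(c(b, -2), 2, 1), h2)
  expect_equal(p, 1 / (1 + exp(-(a - b + 0.5))), tolerance = 1e-12)

  expect_error(predict_interaction(matrix(NaN, 2, 1), matrix(0, 2, 1), hp),
               "finite")
})
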