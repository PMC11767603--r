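## User-facing encoder operations on single sequences.  These wrap the
## batched kernels in nn.R with B = 1 and explicit parameter bundles, so
## the same code paths the trained model uses can be exercised and tested
## in isolation.

#' Embed a tokenized sequence
#'
#' Looks up one embedding row per token; padded positions carry the
#' pad-token embedding.  The validity mask is propagated as an attribute.
#'
#' @param tokens a \code{"dti_tokens"} object.
#' @param table numeric matrix, vocabulary size x embedding dim.
#' @return numeric matrix (max_len x E) with attribute \code{"mask"}.
#' @export
embed_tokens <- function(tokens, table) {
  stopifnot(inherits(tokens, "dti_tokens"), is.matrix(table))
  if (any(tokens$indices < 0L) || any(tokens$indices >= nrow(table)))
    stop2("token index out of range for an embedding table with ",
          nrow(table), " rows")
  Y <- table[tokens$indices + 1L, , drop = FALSE]
  attr(Y, "mask") <- tokens$mask
  Y
}

#' Parameters for a three-layer convolution branch
#'
#' Conv -> ReLU -> Conv -> ReLU -> Conv along the time axis with 'same'
#' padding and stride 1; the final layer carries no activation.  Weights
#' are Glorot-uniform under the given seed, biases zero.
#'
#' @param in_channels input channel count (embedding dim).
#' @param channels output channels of the three layers.
#' @param kernels kernel sizes of the three layers.
#' @param seed initialization seed.
#' @return list of class \code{"dti_conv_params"}.
#' @export
conv_branch_params <- function(in_channels, channels = c(32L, 64L, 96L),
                               kernels = c(4L, 6L, 8L), seed = 1L) {
  stopifnot(length(channels) == 3L, length(kernels) == 3L, all(kernels >= 1L))
  layers <- with_seed(derive_seed(seed, "init"),
                      init_conv_branch(in_channels, channels, kernels))
  structure(c(layers, list(in_channels = as.integer(in_channels),
                           channels = as.integer(channels),
                           kernels = as.integer(kernels))),
            class = "dti_conv_params")
}

#' Apply a three-layer convolution branch to a feature map
#'
#' @param x numeric matrix (T x C_in), time in rows.
#' @param params a \code{\link{conv_branch_params}}.
#' @return numeric matrix (T x channels\[3\]).
#' @export
conv_branch <- function(x, params) {
  stopifnot(inherits(params, "dti_conv_params"), is.matrix(x))
  if (ncol(x) != params$in_channels)
    stop2("input has ", ncol(x), " channels but the branch expects ",
          params$in_channels)
  branch_fwd(x, params, params$kernels, B = 1L, T = nrow(x))$Y
}

#' Encode a drug through two parallel multi-scale convolution branches
#'
#' Both branches consume the same embedded input; their outputs are
#' concatenated along the channel axis (T x 2*channels\[3\]).
#'
#' @param tokens a tokenized SMILES (\code{"dti_tokens"}).
#' @param table embedding table (vocab x E).
#' @param branch1,branch2 \code{\link{conv_branch_params}} for the two
#'   branches (pass the same object for the tied shared-weight mode).
#' @return numeric matrix (max_len x 2*C_out).
#' @export
encode_drug <- function(tokens, table, branch1, branch2) {
  X <- embed_tokens(tokens, table)
  F1 <- conv_branch(X, branch1)
  F2 <- conv_branch(X, branch2)
  if (nrow(F1) != nrow(F2))
    stop2("branch outputs disagree on time length")
  cbind(F1, F2)
}

#' Scaled dot-product attention
#'
#' \code{softmax(Q K' / sqrt(d_k)) V} with optional key masking: masked key
#' positions receive a -Inf logit before the softmax, so every attention
#' row sums to one over the unmasked keys.
#'
#' @param Q queries (n x d_k).
#' @param K keys (m x d_k).
#' @param V values (m x d_v).
#' @param mask optional binary vector of length m; 0 marks masked keys.
#' @return numeric matrix (n x d_v) with the attention matrix attached as
#'   attribute \code{"weights"}.
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop2("Q and K must share d_k")
  if (nrow(K) != nrow(V)) stop2("K and V must have the same number of rows")
  if (!is.null(mask) && length(mask) != nrow(K))
    stop2("mask must have one entry per key")
  a <- attn_core_fwd(Q, K, V, keymask = mask)
  out <- a$Y
  attr(out, "weights") <- a$A
  out
}

#' Parameters for the target transformer encoder
#'
#' Embedding table, sinusoidal positional encoding and \code{n_layers}
#' post-norm transformer blocks (multi-head self-attention and a
#' position-wise feed-forward net, each with residual + layer norm).
#'
#' @param vocab_size subword vocabulary size.
#' @param d_model model width (divisible by \code{n_heads}).
#' @param n_heads attention heads.
#' @param n_layers stacked blocks (0 gives embedding + positional encoding
#'   only).
#' @param ffn_dim feed-forward width.
#' @param seed initialization seed.
#' @return list of class \code{"dti_tf_params"}.
#' @export
transformer_params <- function(vocab_size, d_model = 128L, n_heads = 8L,
                               n_layers = 2L, ffn_dim = 256L, seed = 1L) {
  if (d_model %% n_heads != 0L)
    stop2("d_model must be divisible by n_heads")
  with_seed(derive_seed(seed, "init"), {
    structure(list(embed = matrix(stats::runif(vocab_size * d_model,
                                               -0.1, 0.1),
                                  vocab_size, d_model),
                   layers = lapply(seq_len(n_layers),
                                   function(i) init_tf_layer(d_model, ffn_dim)),
                   d_model = as.integer(d_model),
                   n_heads = as.integer(n_heads),
                   n_layers = as.integer(n_layers),
                   ffn_dim = as.integer(ffn_dim)),
              class = "dti_tf_params")
  })
}

#' Encode a target through the transformer (global) path
#'
#' Embedding plus sinusoidal positional encoding, then the stacked
#' transformer blocks.  Padded positions never contribute as attention
#' keys, so unmasked outputs are invariant to the token values at masked
#' positions.
#'
#' @param tokens a BPE-tokenized protein (\code{"dti_tokens"}).
#' @param params a \code{\link{transformer_params}}.
#' @return numeric matrix (max_tokens x d_model) with attribute
#'   \code{"mask"}.
#' @export
encode_target_transformer <- function(tokens, params) {
  stopifnot(inherits(tokens, "dti_tokens"), inherits(params, "dti_tf_params"))
  if (all(tokens$mask == 0L))
    stop2("cannot encode an empty (all-masked) sequence")
  X <- embed_tokens(tokens, params$embed)
  T <- nrow(X)
  X <- X + positional_encoding(T, params$d_model)
  keymask <- matrix(tokens$mask, 1L, T)
  for (l in seq_len(params$n_layers))
    X <- tf_layer_fwd(X, params$layers[[l]], params$n_heads, 1L, T, keymask)$Y
  attr(X, "mask") <- tokens$mask
  X
}

#' Parameter bundle for the two-path target encoder
#'
#' Character embedding + convolution branch (local path), BPE embedding +
#' transformer (global path), and the linear projections and adaptive
#' pooling that align both to a common (pool_bins x proj_channels) shape.
#'
#' @param char_vocab_size,bpe_vocab_size vocabulary sizes of the two paths.
#' @param embed_dim character embedding width.
#' @param channels,kernels conv branch triples (defaults (32, 64, 96) /
#'   (4, 8, 12)).
#' @param d_model,n_heads,n_layers,ffn_dim transformer geometry.
#' @param proj_channels common channel width C_f.
#' @param pool_bins common time length T_f.
#' @param seed initialization seed.
#' @return list of class \code{"dti_target_params"}.
#' @export
target_encoder_params <- function(char_vocab_size, bpe_vocab_size,
                                  embed_dim = 128L,
                                  channels = c(32L, 64L, 96L),
                                  kernels = c(4L, 8L, 12L),
                                  d_model = 128L, n_heads = 8L,
                                  n_layers = 2L, ffn_dim = 256L,
                                  proj_channels = 96L, pool_bins = 64L,
                                  seed = 1L) {
  tf <- transformer_params(bpe_vocab_size, d_model, n_heads, n_layers,
                           ffn_dim, seed)
  with_seed(derive_seed(seed, "init"), {
    structure(list(char_embed = matrix(stats::runif(char_vocab_size *
                                                      embed_dim, -0.1, 0.1),
                                       char_vocab_size, embed_dim),
                   conv = conv_branch_params(embed_dim, channels, kernels,
                                             seed),
                   tf = tf,
                   proj_L = init_dense(channels[3], proj_channels),
                   proj_G = init_dense(d_model, proj_channels),
                   proj_channels = as.integer(proj_channels),
                   pool_bins = as.integer(pool_bins)),
              class = "dti_target_params")
  })
}

#' Encode a target through both paths and fuse by concatenation
#'
#' Runs the character-level convolution path (local features L) and the
#' BPE transformer path (global features G), aligns both to the common
#' (pool_bins x proj_channels) shape by linear projection and adaptive
#' mean pooling, and concatenates along channels.
#'
#' @param tokens_char character-level tokens of the protein.
#' @param tokens_bpe BPE tokens of the same protein.
#' @param params a \code{\link{target_encoder_params}}.
#' @return list with \code{L} (raw conv features), \code{G} (raw
#'   transformer features) and \code{F_target}
#'   (pool_bins x 2*proj_channels).
#' @export
encode_target <- function(tokens_char, tokens_bpe, params) {
  stopifnot(inherits(params, "dti_target_params"))
  Xc <- embed_tokens(tokens_char, params$char_embed)
  L <- conv_branch(Xc, params$conv)
  G <- encode_target_transformer(tokens_bpe, params$tf)
  if (ncol(L) != nrow(params$proj_L$W))
    stop2("conv output channels (", ncol(L),
          ") do not match the local projection (", nrow(params$proj_L$W), ")")
  if (ncol(G) != nrow(params$proj_G$W))
    stop2("transformer width (", ncol(G),
          ") does not match the global projection (", nrow(params$proj_G$W), ")")
  Tf <- params$pool_bins
  Lp <- dense_fwd(pool_fwd(L, pool_matrix(nrow(L), Tf), 1L, nrow(L)),
                  params$proj_L$W, params$proj_L$b)
  Gp <- dense_fwd(pool_fwd(G, pool_matrix(nrow(G), Tf), 1L, nrow(G)),
                  params$proj_G$W, params$proj_G$b)
  list(L = L, G = G, F_target = cbind(Lp, Gp))
}
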