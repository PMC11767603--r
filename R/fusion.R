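## User-facing fusion-head operations: shared cross attention, the biased
## feature interaction module (BFIM), the selective fusion module (SFM)
## with its squeeze-and-excitation recalibration, and the prediction head.

#' Shared projections for cross attention
#'
#' One (Wq, Wk, Wv) triple serves both attention directions, which is the
#' "shared attention" used to cross the drug and target streams.
#'
#' @param channels common channel width of the two streams.
#' @param seed initialization seed.
#' @return list of class \code{"dti_cross_params"}.
#' @export
cross_attention_params <- function(channels, seed = 1L) {
  with_seed(derive_seed(seed, "init"), {
    structure(list(Wq = glorot(channels, channels), bq = numeric(channels),
                   Wk = glorot(channels, channels), bk = numeric(channels),
                   Wv = glorot(channels, channels), bv = numeric(channels)),
              class = "dti_cross_params")
  })
}

#' Cross drug and target features with shared attention
#'
#' \code{A_t} attends target queries over drug keys/values and \code{A_d}
#' drug queries over target keys/values, with the projection weights
#' shared between the two directions; a residual connection is added on
#' each side.
#'
#' @param F_drug drug feature map (T_d x C).
#' @param F_target target feature map (T_t x C), same channel width.
#' @param params a \code{\link{cross_attention_params}} (or a plain list
#'   with Wq/Wk/Wv and optional biases).
#' @return list with \code{A_d} (T_d x C) and \code{A_t} (T_t x C).
#' @export
shared_cross_attention <- function(F_drug, F_target, params) {
  F_drug <- as.matrix(F_drug); F_target <- as.matrix(F_target)
  if (ncol(F_drug) != ncol(F_target))
    stop2("drug and target maps must share a channel width (got ",
          ncol(F_drug), " and ", ncol(F_target), ")")
  C <- ncol(F_drug)
  bq <- params$bq %||% numeric(C)
  bk <- params$bk %||% numeric(C)
  bv <- params$bv %||% numeric(C)
  proj <- function(X, W, b) add_bias(X %*% W, b)
  Qd <- proj(F_drug, params$Wq, bq); Kd <- proj(F_drug, params$Wk, bk)
  Vd <- proj(F_drug, params$Wv, bv)
  Qt <- proj(F_target, params$Wq, bq); Kt <- proj(F_target, params$Wk, bk)
  Vt <- proj(F_target, params$Wv, bv)
  list(A_d = F_drug + attn_core_fwd(Qd, Kt, Vt)$Y,
       A_t = F_target + attn_core_fwd(Qt, Kd, Vd)$Y)
}

#' Parameters for the biased feature interaction module
#'
#' The default "affine" form concatenates the two streams and their
#' element-wise product and passes them through a bias-bearing affine map
#' with ReLU; the "bilinear" form multiplies two learned projections.
#'
#' @param channels per-stream channel width C_f.
#' @param variant \code{"affine"} or \code{"bilinear"}.
#' @param seed initialization seed.
#' @return list of class \code{"dti_bfim_params"}; output width is
#'   \code{2 * channels}.
#' @export
bfim_params <- function(channels, variant = c("affine", "bilinear"),
                        seed = 1L) {
  variant <- match.arg(variant)
  p <- with_seed(derive_seed(seed, "init"), {
    if (variant == "bilinear")
      list(W1 = glorot(channels, 2L * channels), b1 = numeric(2L * channels),
           W2 = glorot(channels, 2L * channels), b2 = numeric(2L * channels),
           b = numeric(2L * channels))
    else
      list(W = glorot(3L * channels, 2L * channels),
           b = numeric(2L * channels))
  })
  structure(c(p, list(channels = as.integer(channels), variant = variant)),
            class = "dti_bfim_params")
}

#' Biased feature interaction of two aligned streams
#'
#' Position-wise \code{ReLU(W \[A_d ; A_t ; A_d * A_t\] + b)} (affine
#' variant).  The output's two channel halves correspond to the
#' drug-conditioned and target-conditioned streams.
#'
#' @param A_d,A_t aligned feature maps (T x C_f each).
#' @param params a \code{\link{bfim_params}}.
#' @return numeric matrix (T x 2*C_f).
#' @export
bfim <- function(A_d, A_t, params) {
  A_d <- as.matrix(A_d); A_t <- as.matrix(A_t)
  stopifnot(inherits(params, "dti_bfim_params"))
  if (!all(dim(A_d) == dim(A_t)))
    stop2("A_d and A_t must have identical shapes")
  if (ncol(A_d) != params$channels)
    stop2("streams have ", ncol(A_d), " channels; params expect ",
          params$channels)
  bfim_fwd(A_d, A_t, params, params$variant)$Y
}

#' Parameters for the selective fusion module (with SE recalibration)
#'
#' Reduction map W_f (2*C_f -> d_r with d_r = max(2*C_f / r, 4)), the two
#' expansion maps W_u1/W_u2 (d_r -> C_f), and the squeeze-and-excitation
#' bottleneck used to recalibrate the gated output.
#'
#' @param channels per-stream channel width C_f.
#' @param r reduction ratio.
#' @param seed initialization seed.
#' @return list of class \code{"dti_sfm_params"}.
#' @export
sfm_params <- function(channels, r = 4L, seed = 1L) {
  d_r <- max((2L * channels) %/% r, 4L)
  with_seed(derive_seed(seed, "init"), {
    structure(list(Wf = glorot(2L * channels, d_r), bf = numeric(d_r),
                   Wu1 = glorot(d_r, channels), bu1 = numeric(channels),
                   Wu2 = glorot(d_r, channels), bu2 = numeric(channels),
                   se = list(W1 = glorot(2L * channels, d_r),
                             b1 = numeric(d_r),
                             W2 = glorot(d_r, 2L * channels),
                             b2 = numeric(2L * channels)),
                   channels = as.integer(channels), r = as.integer(r)),
              class = "dti_sfm_params")
  })
}

#' Selective fusion of a local and a global stream
#'
#' Concatenates the streams (X = \[L ; G\]), squeezes them by a time mean,
#' reduces through ReLU(W_f I), expands through W_u1/W_u2, and applies a
#' per-channel softmax pair so that the local and global gate for each
#' channel sum to one; the gates weight the original streams.
#'
#' @param L,G feature maps (T x C_f each).
#' @param params a \code{\link{sfm_params}}.
#' @return numeric matrix X_f (T x 2*C_f) with attribute \code{"gates"}
#'   (list of \code{s_L}, \code{s_G}).
#' @export
sfm <- function(L, G, params) {
  L <- as.matrix(L); G <- as.matrix(G)
  stopifnot(inherits(params, "dti_sfm_params"))
  if (!all(dim(L) == dim(G))) stop2("L and G must have identical shapes")
  if (nrow(L) == 0L) stop2("time mean undefined for T = 0")
  if (ncol(L) != params$channels)
    stop2("streams have ", ncol(L), " channels; params expect ",
          params$channels)
  out <- sfm_fwd(L, G, params, B = 1L, T = nrow(L))
  Y <- out$Y
  attr(Y, "gates") <- list(s_L = drop(out$cache$sL), s_G = drop(out$cache$sG))
  Y
}

#' Squeeze-and-excitation recalibration
#'
#' Channel gates \code{sigmoid(W2 ReLU(W1 mean_t(X_f)))} in (0, 1),
#' multiplied into the feature map.
#'
#' @param X_f feature map (T x 2*C_f).
#' @param params a \code{\link{sfm_params}} (its \code{se} block is used).
#' @return gated matrix of the same shape with attribute \code{"gates"}.
#' @export
se_recalibrate <- function(X_f, params) {
  X_f <- as.matrix(X_f)
  stopifnot(inherits(params, "dti_sfm_params"))
  if (nrow(X_f) == 0L) stop2("time mean undefined for T = 0")
  out <- se_fwd(X_f, params$se, B = 1L, T = nrow(X_f))
  Y <- out$Y
  attr(Y, "gates") <- drop(out$cache$E)
  Y
}

#' Parameters for the fully connected prediction head
#'
#' @param in_dim input width (pooled drug + selected features).
#' @param widths hidden widths; a final 1-unit sigmoid layer is appended.
#' @param dropout dropout rate between hidden layers (training only; the
#'   head is evaluated deterministically here).
#' @param seed initialization seed.
#' @return list of class \code{"dti_head_params"}.
#' @export
head_params <- function(in_dim, widths = c(512L, 128L), dropout = 0.1,
                        seed = 1L) {
  all_w <- c(as.integer(in_dim), as.integer(widths), 1L)
  layers <- with_seed(derive_seed(seed, "init"),
                      lapply(seq_len(length(all_w) - 1L), function(i)
                        init_dense(all_w[i], all_w[i + 1])))
  structure(list(layers = layers, in_dim = as.integer(in_dim),
                 dropout = dropout),
            class = "dti_head_params")
}

#' Interaction probability from drug and selected features
#'
#' Global max pooling over time on both maps, concatenation, and the fully
#' connected stack with a sigmoid output unit; evaluated deterministically
#' (dropout disabled).
#'
#' @param F_drug drug feature map (T_d x C_d).
#' @param F_select selected feature map (T_f x C_s).
#' @param head a \code{\link{head_params}} with
#'   \code{in_dim = C_d + C_s}.
#' @return a single probability in \[0, 1\].
#' @export
predict_interaction <- function(F_drug, F_select, head) {
  F_drug <- as.matrix(F_drug); F_select <- as.matrix(F_select)
  stopifnot(inherits(head, "dti_head_params"))
  if (!all(is.finite(F_drug)) || !all(is.finite(F_select)))
    stop2("inputs must be finite")
  u <- c(apply(F_drug, 2L, max), apply(F_select, 2L, max))
  if (length(u) != head$in_dim)
    stop2("pooled feature width ", length(u), " does not match head input ",
          head$in_dim)
  H <- matrix(u, 1L)
  n <- length(head$layers)
  for (i in seq_len(n - 1L))
    H <- relu_fwd(dense_fwd(H, head$layers[[i]]$W, head$layers[[i]]$b))
  z <- dense_fwd(H, head$layers[[n]]$W, head$layers[[n]]$b)
  1 / (1 + exp(-drop(z)))
}
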