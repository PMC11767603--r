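## Full model: drug multi-scale CNN branches, target conv + transformer
## paths, shared cross attention, biased feature interaction (BFIM),
## selective fusion (SFM) with squeeze-and-excitation, and the fully
## connected head.  Forward and backward passes are assembled here from
## the primitives in nn.R; ablation variants toggle components.

variant_plan <- function(variant) {
  switch(variant,
    mcf_dti = list(drug = "mscnn2", target = "both", fusion = "mcf"),
    mscnn_mscnn = list(drug = "mscnn1", target = "conv", fusion = "concat"),
    mscnn_transformer = list(drug = "mscnn1", target = "transformer",
                             fusion = "concat"),
    mscnn2_mscnn2 = list(drug = "mscnn2", target = "conv2", fusion = "concat"),
    mscnn2_mscnn_transformer_s = list(drug = "mscnn2", target = "both",
                                      fusion = "concat"),
    cnn_transformer = list(drug = "cnn", target = "transformer",
                           fusion = "concat"),
    mscnn_mscnn_transformer_c = list(drug = "mscnn1", target = "both",
                                     fusion = "concat"),
    stop2("unknown architecture variant: ", variant))
}

plan_uses_conv <- function(plan) plan$target %in% c("conv", "conv2", "both")
plan_uses_tf <- function(plan) plan$target %in% c("transformer", "both")

model_dims <- function(mcfg, plan) {
  c3d <- mcfg$drug_channels[3]
  C_d <- if (plan$drug == "mscnn2") 2L * c3d else c3d
  C_f <- mcfg$proj_channels
  n_streams <- (plan$target %in% c("conv", "both")) +
    (plan$target == "conv2") * 2L + plan_uses_tf(plan)
  head_in <- if (plan$fusion == "mcf") C_d + 2L * C_f
             else C_d + n_streams * C_f
  list(C_d = C_d, C_f = C_f, head_in = head_in,
       drug_kernels = if (plan$drug == "cnn")
         rep(mcfg$drug_kernels[1], 3L) else mcfg$drug_kernels)
}

init_conv_branch <- function(in_ch, channels, kernels) {
  chans <- c(in_ch, channels)
  out <- list()
  for (i in 1:3) {
    out[[paste0("conv", i)]] <-
      list(W = glorot(kernels[i] * chans[i], chans[i + 1]),
           b = numeric(chans[i + 1]))
  }
  out
}

init_dense <- function(nin, nout) list(W = glorot(nin, nout), b = numeric(nout))

init_tf_layer <- function(d, ffn) {
  list(Wq = glorot(d, d), bq = numeric(d), Wk = glorot(d, d), bk = numeric(d),
       Wv = glorot(d, d), bv = numeric(d), Wo = glorot(d, d), bo = numeric(d),
       g1 = rep(1, d), nb1 = numeric(d),
       W1 = glorot(d, ffn), fb1 = numeric(ffn),
       W2 = glorot(ffn, d), fb2 = numeric(d),
       g2 = rep(1, d), nb2 = numeric(d))
}

init_params <- function(mcfg, plan, n_smiles, n_prot, n_bpe, seed) {
  dims <- model_dims(mcfg, plan)
  E <- mcfg$embed_dim; d <- mcfg$d_model; C_f <- dims$C_f
  d_r <- max((2L * C_f) %/% mcfg$se_ratio, 4L)
  with_seed(derive_seed(seed, "init"), {
    p <- list()
    p$drug_embed <- matrix(stats::runif(n_smiles * E, -0.1, 0.1), n_smiles, E)
    p$drug_b1 <- init_conv_branch(E, mcfg$drug_channels, dims$drug_kernels)
    if (plan$drug == "mscnn2" && !mcfg$share_drug_branch_weights)
      p$drug_b2 <- init_conv_branch(E, mcfg$drug_channels, dims$drug_kernels)
    if (plan_uses_conv(plan)) {
      p$tgt_embed <- matrix(stats::runif(n_prot * E, -0.1, 0.1), n_prot, E)
      p$tgt_b1 <- init_conv_branch(E, mcfg$target_channels, mcfg$target_kernels)
      if (plan$target == "conv2")
        p$tgt_b2 <- init_conv_branch(E, mcfg$target_channels,
                                     mcfg$target_kernels)
      p$proj_L <- init_dense(mcfg$target_channels[3], C_f)
      if (plan$target == "conv2")
        p$proj_L2 <- init_dense(mcfg$target_channels[3], C_f)
    }
    if (plan_uses_tf(plan)) {
      p$bpe_embed <- matrix(stats::runif(n_bpe * d, -0.1, 0.1), n_bpe, d)
      p$tf <- lapply(seq_len(mcfg$n_layers),
                     function(i) init_tf_layer(d, mcfg$ffn_dim))
      p$proj_G <- init_dense(d, C_f)
    }
    if (plan$fusion == "mcf") {
      p$proj_D <- init_dense(dims$C_d, C_f)
      p$proj_T <- init_dense(2L * C_f, C_f)
      p$cross <- list(Wq = glorot(C_f, C_f), bq = numeric(C_f),
                      Wk = glorot(C_f, C_f), bk = numeric(C_f),
                      Wv = glorot(C_f, C_f), bv = numeric(C_f))
      p$bfim <- if (mcfg$bfim_variant == "bilinear")
        list(W1 = glorot(C_f, 2L * C_f), b1 = numeric(2L * C_f),
             W2 = glorot(C_f, 2L * C_f), b2 = numeric(2L * C_f),
             b = numeric(2L * C_f))
      else list(W = glorot(3L * C_f, 2L * C_f), b = numeric(2L * C_f))
      p$sfm <- list(Wf = glorot(2L * C_f, d_r), bf = numeric(d_r),
                    Wu1 = glorot(d_r, C_f), bu1 = numeric(C_f),
                    Wu2 = glorot(d_r, C_f), bu2 = numeric(C_f))
      p$se <- list(W1 = glorot(2L * C_f, d_r), b1 = numeric(d_r),
                   W2 = glorot(d_r, 2L * C_f), b2 = numeric(2L * C_f))
    }
    widths <- c(dims$head_in, mcfg$head_widths, 1L)
    p$head <- lapply(seq_len(length(widths) - 1L),
                     function(i) init_dense(widths[i], widths[i + 1]))
    p
  })
}

## Forward pass over one batch.  batch: list(drug_tok, prot_tok, bpe_tok,
## bpe_mask) with one row per sample; returns logits and a cache for the
## backward pass.
model_forward <- function(params, batch, mcfg, plan, training = FALSE) {
  B <- nrow(batch$drug_tok)
  Td <- mcfg$smiles_max_len; Tp <- mcfg$protein_max_len
  Tb <- mcfg$bpe_max_tokens; Tf <- mcfg$pool_bins
  ca <- list(B = B)
  tied <- plan$drug == "mscnn2" && mcfg$share_drug_branch_weights
  dims <- model_dims(mcfg, plan)

  ## ---- drug encoder
  ca$emb_d <- embed_fwd(batch$drug_tok, params$drug_embed)
  ca$br1 <- branch_fwd(ca$emb_d$Y, params$drug_b1, dims$drug_kernels, B, Td)
  if (plan$drug == "mscnn2") {
    p2 <- if (tied) params$drug_b1 else params$drug_b2
    ca$br2 <- branch_fwd(ca$emb_d$Y, p2, dims$drug_kernels, B, Td)
    F_drug <- cbind(ca$br1$Y, ca$br2$Y)
  } else F_drug <- ca$br1$Y
  ca$F_drug <- F_drug

  ## ---- target local (conv) path
  streams <- list()
  if (plan_uses_conv(plan)) {
    ca$emb_t <- embed_fwd(batch$prot_tok, params$tgt_embed)
    ca$tb1 <- branch_fwd(ca$emb_t$Y, params$tgt_b1, mcfg$target_kernels, B, Tp)
    ca$P_Tp <- pool_matrix(Tp, Tf)
    ca$L_pool <- pool_fwd(ca$tb1$Y, ca$P_Tp, B, Tp)
    ca$Lp <- dense_fwd(ca$L_pool, params$proj_L$W, params$proj_L$b)
    streams$Lp <- ca$Lp
    if (plan$target == "conv2") {
      ca$tb2 <- branch_fwd(ca$emb_t$Y, params$tgt_b2, mcfg$target_kernels, B, Tp)
      ca$L2_pool <- pool_fwd(ca$tb2$Y, ca$P_Tp, B, Tp)
      ca$L2p <- dense_fwd(ca$L2_pool, params$proj_L2$W, params$proj_L2$b)
      streams$L2p <- ca$L2p
    }
  }

  ## ---- target global (transformer) path
  if (plan_uses_tf(plan)) {
    if (any(rowSums(batch$bpe_mask) == 0))
      stop2("a protein produced an empty (all-masked) subword sequence")
    ca$emb_b <- embed_fwd(batch$bpe_tok, params$bpe_embed)
    pe <- positional_encoding(Tb, mcfg$d_model)
    X <- ca$emb_b$Y + pe[rep(seq_len(Tb), B), , drop = FALSE]
    ca$tf_in <- X
    ca$tf_layers <- vector("list", mcfg$n_layers)
    for (l in seq_len(mcfg$n_layers)) {
      lf <- tf_layer_fwd(X, params$tf[[l]], mcfg$n_heads, B, Tb,
                         batch$bpe_mask)
      ca$tf_layers[[l]] <- lf$cache
      X <- lf$Y
    }
    ca$G <- X
    ca$P_Tb <- pool_matrix(Tb, Tf)
    ca$G_pool <- pool_fwd(X, ca$P_Tb, B, Tb)
    ca$Gp <- dense_fwd(ca$G_pool, params$proj_G$W, params$proj_G$b)
    streams$Gp <- ca$Gp
  }

  ## ---- fusion
  if (plan$fusion == "mcf") {
    ca$P_Td <- pool_matrix(Td, Tf)
    ca$D_pool <- pool_fwd(F_drug, ca$P_Td, B, Td)
    ca$Dp <- dense_fwd(ca$D_pool, params$proj_D$W, params$proj_D$b)
    if (mcfg$sfm_on_target_LG) {
      ca$sfm <- sfm_fwd(ca$Lp, ca$Gp, params$sfm, B, Tf)
      ca$se <- se_fwd(ca$sfm$Y, params$se, B, Tf)
      Tcomb <- ca$se$Y
    } else Tcomb <- cbind(ca$Lp, ca$Gp)
    ca$Tcomb <- Tcomb
    ca$Tt <- dense_fwd(Tcomb, params$proj_T$W, params$proj_T$b)
    ca$cross <- cross_fwd(ca$Dp, ca$Tt, params$cross, B, Tf)
    ca$bfim <- bfim_fwd(ca$cross$Ad, ca$cross$At, params$bfim,
                        mcfg$bfim_variant)
    if (!mcfg$sfm_on_target_LG) {
      C_f <- dims$C_f
      ca$sfm <- sfm_fwd(ca$bfim$Y[, seq_len(C_f), drop = FALSE],
                        ca$bfim$Y[, C_f + seq_len(C_f), drop = FALSE],
                        params$sfm, B, Tf)
      ca$se <- se_fwd(ca$sfm$Y, params$se, B, Tf)
      F_select <- ca$se$Y
    } else F_select <- ca$bfim$Y
    ca$F_select <- F_select
    ca$gm_sel <- gmax_fwd(F_select, B, Tf)
    ca$gm_drug <- gmax_fwd(F_drug, B, Td)
    U <- cbind(ca$gm_drug$Y, ca$gm_sel$Y)
  } else {
    ca$gm_drug <- gmax_fwd(F_drug, B, Td)
    parts <- list(ca$gm_drug$Y)
    ca$gm_streams <- lapply(streams, function(S)
      gmax_fwd(S, B, Tf))
    parts <- c(parts, lapply(ca$gm_streams, `[[`, "Y"))
    U <- do.call(cbind, parts)
  }
  ca$U <- U

  ## ---- fully connected head
  n_hidden <- length(params$head) - 1L
  H <- U
  ca$head <- vector("list", length(params$head))
  for (i in seq_len(n_hidden)) {
    Z <- dense_fwd(H, params$head[[i]]$W, params$head[[i]]$b)
    A <- relu_fwd(Z)
    dr <- dropout_fwd(A, mcfg$dropout, training)
    ca$head[[i]] <- list(X = H, Z = Z, A = A, mask = dr$mask)
    H <- dr$Y
  }
  i <- length(params$head)
  Z <- dense_fwd(H, params$head[[i]]$W, params$head[[i]]$b)
  ca$head[[i]] <- list(X = H)
  list(logits = as.vector(Z), cache = ca)
}

## Backward pass: dlogits is the gradient of the loss w.r.t. the logits
## (length B).  Returns the parameter-gradient tree.
model_backward <- function(params, ca, dlogits, batch, mcfg, plan) {
  B <- ca$B
  Td <- mcfg$smiles_max_len; Tp <- mcfg$protein_max_len
  Tb <- mcfg$bpe_max_tokens; Tf <- mcfg$pool_bins
  dims <- model_dims(mcfg, plan)
  tied <- plan$drug == "mscnn2" && mcfg$share_drug_branch_weights
  g <- list()

  ## ---- head
  dZ <- matrix(dlogits, ncol = 1L)
  n_head <- length(params$head)
  g$head <- vector("list", n_head)
  for (i in rev(seq_len(n_head))) {
    hc <- ca$head[[i]]
    gd <- dense_bwd(dZ, hc$X, params$head[[i]]$W)
    g$head[[i]] <- list(W = gd$dW, b = gd$db)
    dH <- gd$dX
    if (i > 1L) {
      hp <- ca$head[[i - 1L]]
      dH <- dropout_bwd(dH, hp$mask)
      dZ <- relu_bwd(dH, hp$Z)
    } else dU <- dH
  }

  ## ---- split the pooled feature vector
  C_d <- dims$C_d; C_f <- dims$C_f
  dgm_drug <- dU[, seq_len(C_d), drop = FALSE]
  dF_drug <- gmax_bwd(dgm_drug, ca$gm_drug$idx, B * Td)
  dLp <- NULL; dL2p <- NULL; dGp <- NULL

  if (plan$fusion == "mcf") {
    dgm_sel <- dU[, C_d + seq_len(2L * C_f), drop = FALSE]
    dF_select <- gmax_bwd(dgm_sel, ca$gm_sel$idx, B * Tf)
    if (!mcfg$sfm_on_target_LG) {
      se_g <- se_bwd(dF_select, ca$se$cache, params$se, B, Tf)
      g$se <- se_g$grads
      sfm_g <- sfm_bwd(se_g$dX, ca$sfm$cache, params$sfm, B, Tf)
      g$sfm <- sfm_g$grads
      dFcross <- cbind(sfm_g$dL, sfm_g$dG)
    } else dFcross <- dF_select
    bf_g <- bfim_bwd(dFcross, ca$bfim$cache, params$bfim, mcfg$bfim_variant)
    g$bfim <- bf_g$grads
    cr_g <- cross_bwd(bf_g$dAd, bf_g$dAt, ca$cross$cache, params$cross, B, Tf)
    g$cross <- cr_g$grads
    gt <- dense_bwd(cr_g$dTt, ca$Tcomb, params$proj_T$W)
    g$proj_T <- list(W = gt$dW, b = gt$db)
    if (mcfg$sfm_on_target_LG) {
      se_g <- se_bwd(gt$dX, ca$se$cache, params$se, B, Tf)
      g$se <- se_g$grads
      sfm_g <- sfm_bwd(se_g$dX, ca$sfm$cache, params$sfm, B, Tf)
      g$sfm <- sfm_g$grads
      dLp <- sfm_g$dL; dGp <- sfm_g$dG
    } else {
      dLp <- gt$dX[, seq_len(C_f), drop = FALSE]
      dGp <- gt$dX[, C_f + seq_len(C_f), drop = FALSE]
    }
    gd <- dense_bwd(cr_g$dD, ca$D_pool, params$proj_D$W)
    g$proj_D <- list(W = gd$dW, b = gd$db)
    dF_drug <- dF_drug + pool_bwd(gd$dX, ca$P_Td, B, Td)
  } else {
    off <- C_d
    for (nm in names(ca$gm_streams)) {
      dgm <- dU[, off + seq_len(C_f), drop = FALSE]
      off <- off + C_f
      dS <- gmax_bwd(dgm, ca$gm_streams[[nm]]$idx, B * Tf)
      if (nm == "Lp") dLp <- dS
      else if (nm == "L2p") dL2p <- dS
      else if (nm == "Gp") dGp <- dS
    }
  }

  ## ---- target transformer path
  if (plan_uses_tf(plan) && !is.null(dGp)) {
    gg <- dense_bwd(dGp, ca$G_pool, params$proj_G$W)
    g$proj_G <- list(W = gg$dW, b = gg$db)
    dX <- pool_bwd(gg$dX, ca$P_Tb, B, Tb)
    g$tf <- vector("list", mcfg$n_layers)
    for (l in rev(seq_len(mcfg$n_layers))) {
      lb <- tf_layer_bwd(dX, ca$tf_layers[[l]], params$tf[[l]],
                         mcfg$n_heads, B, Tb)
      g$tf[[l]] <- lb$grads
      dX <- lb$dX
    }
    g$bpe_embed <- embed_bwd(dX, ca$emb_b$ids, nrow(params$bpe_embed),
                             mcfg$d_model)
  }

  ## ---- target conv path
  if (plan_uses_conv(plan) && !is.null(dLp)) {
    gl <- dense_bwd(dLp, ca$L_pool, params$proj_L$W)
    g$proj_L <- list(W = gl$dW, b = gl$db)
    dL <- pool_bwd(gl$dX, ca$P_Tp, B, Tp)
    tb <- branch_bwd(dL, ca$tb1$cache, params$tgt_b1, mcfg$target_kernels)
    g$tgt_b1 <- tb$grads
    dEmb_t <- tb$dX
    if (plan$target == "conv2" && !is.null(dL2p)) {
      gl2 <- dense_bwd(dL2p, ca$L2_pool, params$proj_L2$W)
      g$proj_L2 <- list(W = gl2$dW, b = gl2$db)
      dL2 <- pool_bwd(gl2$dX, ca$P_Tp, B, Tp)
      tb2 <- branch_bwd(dL2, ca$tb2$cache, params$tgt_b2, mcfg$target_kernels)
      g$tgt_b2 <- tb2$grads
      dEmb_t <- dEmb_t + tb2$dX
    }
    g$tgt_embed <- embed_bwd(dEmb_t, ca$emb_t$ids, nrow(params$tgt_embed),
                             mcfg$embed_dim)
  }

  ## ---- drug branches
  C3 <- mcfg$drug_channels[3]
  d1 <- dF_drug[, seq_len(C3), drop = FALSE]
  b1g <- branch_bwd(d1, ca$br1$cache, params$drug_b1, dims$drug_kernels)
  dEmb_d <- b1g$dX
  g$drug_b1 <- b1g$grads
  if (plan$drug == "mscnn2") {
    d2 <- dF_drug[, C3 + seq_len(C3), drop = FALSE]
    p2 <- if (tied) params$drug_b1 else params$drug_b2
    b2g <- branch_bwd(d2, ca$br2$cache, p2, dims$drug_kernels)
    dEmb_d <- dEmb_d + b2g$dX
    if (tied) g$drug_b1 <- grad_add(g$drug_b1, b2g$grads)
    else g$drug_b2 <- b2g$grads
  }
  g$drug_embed <- embed_bwd(dEmb_d, ca$emb_d$ids, nrow(params$drug_embed),
                            mcfg$embed_dim)
  g
}

binary_xent <- function(logits, y) {
  ## numerically stable mean BCE on logits
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

## protein validation: any symbol outside the 20 standard letters becomes
## '?' before character tokenization and BPE
clean_protein <- function(x) gsub("[^ACDEFGHIKLMNPQRSTVWY]", "?", x)

tokenize_records <- function(records, vocab_smiles, bpe, mcfg) {
  N <- nrow(records)
  drug_tok <- matrix(0L, N, mcfg$smiles_max_len)
  prot_tok <- matrix(0L, N, mcfg$protein_max_len)
  bpe_tok <- matrix(0L, N, mcfg$bpe_max_tokens)
  bpe_mask <- matrix(0L, N, mcfg$bpe_max_tokens)
  vocab_prot <- amino_acid_vocabulary()
  for (i in seq_len(N)) {
    drug_tok[i, ] <- tokenize_chars(records$smiles[i], vocab_smiles,
                                    mcfg$smiles_max_len)$indices
    prot_tok[i, ] <- tokenize_chars(records$sequence[i], vocab_prot,
                                    mcfg$protein_max_len,
                                    allowed = AA_LETTERS)$indices
  }
  useq <- unique(records$sequence)
  enc <- encode_bpe_corpus(clean_protein(useq), bpe, mcfg$bpe_max_tokens)
  pos <- match(records$sequence, useq)
  for (i in seq_len(N)) {
    bpe_tok[i, ] <- enc[[pos[i]]]$indices
    bpe_mask[i, ] <- enc[[pos[i]]]$mask
  }
  list(drug_tok = drug_tok, prot_tok = prot_tok,
       bpe_tok = bpe_tok, bpe_mask = bpe_mask)
}

#' Fit the drug-target interaction model
#'
#' Trains the multi-scale convolutional / transformer fusion classifier on
#' labelled drug-target pairs with Adam and binary cross-entropy.  The
#' SMILES vocabulary and the protein BPE model are built from the supplied
#' (training) records, so fitting on a training fold leaks nothing from
#' held-out data.  All randomness (initialization, shuffling, dropout)
#' derives from \code{train_cfg$seed}; two fits with identical inputs and
#' seed are bit-identical.
#'
#' @param records data.frame with columns \code{smiles}, \code{sequence},
#'   \code{label} (0/1); typically from \code{\link{generate_pairs}},
#'   \code{\link{read_pairs_tsv}} or the Davis loader pipeline.
#' @param model_cfg a \code{\link{model_config}} /
#'   \code{\link{small_model_config}}.
#' @param train_cfg a \code{\link{train_config}}.
#' @param verbose print per-epoch loss.
#' @return An object of class \code{"mcf_dti"}: the trained parameters,
#'   tokenization artifacts, per-epoch loss history and training-set
#'   fitted probabilities.  Methods: \code{print}, \code{summary},
#'   \code{predict}, \code{plot}, \code{coef}, \code{residuals}.
#' @examples
#' \donttest{
#' sp <- synthetic_spec(n_drugs = 20, n_targets = 15, seed = 7)
#' recs <- generate_pairs(sp, 120)$records
#' fit <- mcf_dti(recs, small_model_config(),
#'                train_config(epochs = 2, seed = 7))
#' head(predict(fit, recs))
#' }
#' @export
mcf_dti <- function(records, model_cfg = model_config(),
                    train_cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model_cfg, "dti_model_config"),
            inherits(train_cfg, "dti_train_config"))
  if (is.null(records$label)) stop2("records must carry a binary label column")
  y <- as.numeric(records$label)
  if (any(!(y %in% c(0, 1)))) stop2("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop2("training needs at least one record of each class")
  plan <- variant_plan(train_cfg$architecture_variant)

  vocab_smiles <- build_smiles_vocabulary(records$smiles)
  bpe <- if (plan_uses_tf(plan))
    train_bpe(clean_protein(unique(records$sequence)), model_cfg$bpe_merges)
  else train_bpe(clean_protein(unique(records$sequence)), 0L)
  toks <- tokenize_records(records, vocab_smiles, bpe, model_cfg)

  params <- init_params(model_cfg, plan, vocab_smiles$size,
                        amino_acid_vocabulary()$size, bpe$vocab$size,
                        train_cfg$seed)
  state <- adam_init(params)
  N <- nrow(records)
  bs <- min(train_cfg$batch_size, N)
  history <- numeric(0)
  best <- Inf; since_best <- 0L

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(derive_seed(train_cfg$seed, "train"))
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  for (ep in seq_len(train_cfg$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, N, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, N)]
      batch <- list(drug_tok = toks$drug_tok[idx, , drop = FALSE],
                    prot_tok = toks$prot_tok[idx, , drop = FALSE],
                    bpe_tok = toks$bpe_tok[idx, , drop = FALSE],
                    bpe_mask = toks$bpe_mask[idx, , drop = FALSE])
      fw <- model_forward(params, batch, model_cfg, plan, training = TRUE)
      loss <- binary_xent(fw$logits, y[idx])
      if (!is.finite(loss))
        stop2("training diverged to a non-finite loss at epoch ", ep,
              " (batch starting at ", start, "); lower the learning rate")
      prob <- 1 / (1 + exp(-fw$logits))
      dlogits <- (prob - y[idx]) / length(idx)
      grads <- model_backward(params, fw$cache, dlogits, batch, model_cfg, plan)
      st <- adam_step(params, grads, state, train_cfg$learning_rate)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    history <- c(history, ep_loss / nb)
    if (verbose) message(sprintf("epoch %d  loss %.5f", ep, ep_loss / nb))
    if (train_cfg$early_stopping) {
      if (ep_loss / nb < best - 1e-6) { best <- ep_loss / nb; since_best <- 0L }
      else since_best <- since_best + 1L
      if (since_best >= train_cfg$patience) break
    }
  }

  fit <- structure(list(params = params, vocab_smiles = vocab_smiles,
                        bpe = bpe, model_cfg = model_cfg,
                        train_cfg = train_cfg, plan = plan,
                        loss_history = history,
                        n_train = N, call = match.call()),
                   class = "mcf_dti")
  fit$fitted <- predict(fit, records)
  fit$train_labels <- y
  fit
}

predict_tokens <- function(fit, toks, batch_size = 64L) {
  N <- nrow(toks$drug_tok)
  probs <- numeric(N)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    batch <- lapply(toks, function(M) M[idx, , drop = FALSE])
    fw <- model_forward(fit$params, batch, fit$model_cfg, fit$plan,
                        training = FALSE)
    probs[idx] <- 1 / (1 + exp(-fw$logits))
  }
  probs
}

#' Predict interaction probabilities
#'
#' @param object a fitted \code{"mcf_dti"} model.
#' @param newdata records data.frame with \code{smiles} and \code{sequence}
#'   columns.
#' @param type \code{"response"} (probabilities) or \code{"class"}
#'   (0/1 at the configured decision threshold).
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return numeric (or integer) vector, one value per row of
#'   \code{newdata}.
#' @export
predict.mcf_dti <- function(object, newdata, type = c("response", "class"),
                            batch_size = 64L, ...) {
  type <- match.arg(type)
  if (is.null(newdata$smiles) || is.null(newdata$sequence))
    stop2("newdata must have smiles and sequence columns")
  toks <- tokenize_records(newdata, object$vocab_smiles, object$bpe,
                           object$model_cfg)
  probs <- predict_tokens(object, toks, batch_size)
  if (type == "class") as.integer(probs >= object$train_cfg$decision_threshold)
  else probs
}

#' @export
print.mcf_dti <- function(x, ...) {
  cat("Drug-target interaction model (", x$train_cfg$architecture_variant,
      ")\n", sep = "")
  cat("  trained on", x$n_train, "pairs for", length(x$loss_history),
      "epochs; final loss",
      if (length(x$loss_history)) sprintf("%.4f", utils::tail(x$loss_history, 1))
      else "(untrained)", "\n")
  cat("  SMILES vocabulary:", x$vocab_smiles$size, "tokens; BPE:",
      x$bpe$num_merges, "merges\n")
  invisible(x)
}

#' @export
summary.mcf_dti <- function(object, ...) {
  npar <- 0
  count <- function(x) if (is.list(x)) sum(vapply(x, count, 0)) else length(x)
  npar <- count(object$params)
  thr <- object$train_cfg$decision_threshold
  tm <- threshold_metrics(object$train_labels, object$fitted, thr)
  out <- list(variant = object$train_cfg$architecture_variant,
              n_parameters = npar, n_train = object$n_train,
              epochs = length(object$loss_history),
              final_loss = utils::tail(object$loss_history, 1),
              train_auc = auc_score(object$train_labels, object$fitted),
              train_accuracy = tm$accuracy)
  class(out) <- "summary.mcf_dti"
  out
}

#' @export
print.summary.mcf_dti <- function(x, ...) {
  cat("DTI model summary\n")
  cat("  variant:       ", x$variant, "\n")
  cat("  parameters:    ", format(x$n_parameters, big.mark = ","), "\n")
  cat("  training pairs:", x$n_train, "over", x$epochs, "epochs\n")
  if (length(x$final_loss))
    cat("  final loss:    ", sprintf("%.4f", x$final_loss), "\n")
  cat("  training AUC:  ", sprintf("%.4f", x$train_auc),
      "  accuracy:", sprintf("%.4f", x$train_accuracy), "\n")
  invisible(x)
}

#' @export
plot.mcf_dti <- function(x, ...) {
  if (!length(x$loss_history)) stop2("no training history to plot")
  plot(seq_along(x$loss_history), x$loss_history, type = "l",
       xlab = "epoch", ylab = "training loss (BCE)",
       main = "Training loss", ...)
  invisible(x)
}

#' @export
coef.mcf_dti <- function(object, ...) object$params

#' @export
residuals.mcf_dti <- function(object, ...) object$train_labels - object$fitted
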