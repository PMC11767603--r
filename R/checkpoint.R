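## Plain-text checkpointing: parameters and tokenization artifacts go to a
## single JSON document so a fitted model can be stored and reloaded
## without binary serialization.

encode_tree <- function(x) {
  if (is.list(x)) lapply(x, encode_tree)
  else list(.dim = dim(x) %||% length(x), .val = as.vector(x))
}

decode_tree <- function(x) {
  if (is.list(x) && !is.null(x$.val)) {
    v <- as.numeric(x$.val)
    d <- as.integer(x$.dim)
    if (length(d) == 2L) matrix(v, d[1], d[2]) else v
  } else lapply(x, decode_tree)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is one JSON document holding the parameters, the SMILES
#' vocabulary, the BPE merges and both configurations.  On load, the
#' embedding-table shapes are checked against the stored vocabularies; a
#' checkpoint paired with an incompatible vocabulary is rejected.
#'
#' @param fit a fitted \code{"mcf_dti"}.
#' @param path checkpoint file (.json).
#' @return \code{save_checkpoint}: \code{path} invisibly;
#'   \code{load_checkpoint}: an \code{"mcf_dti"} object.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "mcf_dti"))
  doc <- list(params = encode_tree(fit$params),
              vocab_tokens = fit$vocab_smiles$tokens,
              bpe_merges = lapply(fit$bpe$merges, as.character),
              bpe_tokens = fit$bpe$vocab$tokens,
              model_cfg = unclass(fit$model_cfg),
              train_cfg = unclass(fit$train_cfg),
              loss_history = fit$loss_history,
              n_train = fit$n_train)
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  mcfg <- do.call(model_config,
                  doc$model_cfg[intersect(names(doc$model_cfg),
                                          names(formals(model_config)))])
  tcfg <- do.call(train_config,
                  doc$train_cfg[intersect(names(doc$train_cfg),
                                          names(formals(train_config)))])
  vocab <- vocabulary(doc$vocab_tokens)
  merges <- if (length(doc$bpe_merges)) {
    if (is.matrix(doc$bpe_merges))
      apply(doc$bpe_merges, 1L, as.character, simplify = FALSE)
    else lapply(doc$bpe_merges, as.character)
  } else list()
  bpe <- structure(list(merges = merges, vocab = vocabulary(doc$bpe_tokens),
                        num_merges = length(merges)),
                   class = "dti_bpe")
  params <- decode_tree(doc$params)
  if (nrow(params$drug_embed) != vocab$size)
    stop2("checkpoint is incompatible with its vocabulary: embedding has ",
          nrow(params$drug_embed), " rows for ", vocab$size, " tokens")
  if (!is.null(params$bpe_embed) &&
      nrow(params$bpe_embed) != bpe$vocab$size)
    stop2("checkpoint is incompatible with its BPE vocabulary")
  if (!identical(vocab$tokens, as.character(doc$vocab_tokens)))
    stop2("checkpoint vocabulary is not in canonical order")
  fit <- structure(list(params = params, vocab_smiles = vocab, bpe = bpe,
                        model_cfg = mcfg, train_cfg = tcfg,
                        plan = variant_plan(tcfg$architecture_variant),
                        loss_history = as.numeric(doc$loss_history),
                        n_train = doc$n_train %||% NA_integer_),
                   class = "mcf_dti")
  fit
}
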