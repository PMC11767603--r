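test_that("analytic gradients match finite differences through the full model", {
  cfg <- tiny_model_config()
  set.seed(42)
  B <- 3L
  batch <- list(
    drug_tok = matrix(sample(0:6, B * cfg$smiles_max_len, TRUE), B),
    prot_tok = matrix(sample(0:20, B * cfg$protein_max_len, TRUE), B),
    bpe_tok = matrix(sample(0:8, B * cfg$bpe_max_tokens, TRUE), B),
    bpe_mask = rbind(c(1, 1, 1, 1, 0, 0), rep(1L, 6), c(1, 1, 0, 0, 0, 0)))
  y <- c(1, 0, 1)
  set_in <- function(tr, path, i, d) {
    if (length(path) == 1L) { tr[[path]][i] <- tr[[path]][i] + d; tr }
    else { tr[[path[1]]] <- set_in(tr[[path[1]]], path[-1], i, d); tr }
  }
  for (variant in c("mcf_dti", "mscnn_mscnn_transformer_c")) {
    plan <- mcfdti:::variant_plan(variant)
    params <- jitter_params(
      mcfdti:::init_params(cfg, plan, 7L, 21L, 9L, seed = 5L))
    lossfn <- function(p) {
      fw <- mcfdti:::model_forward(p, batch, cfg, plan, training = FALSE)
      mcfdti:::binary_xent(fw$logits, y)
    }
    fw <- mcfdti:::model_forward(params, batch, cfg, plan, training = FALSE)
    dlogits <- (1 / (1 + exp(-fw$logits)) - y) / length(y)
    grads <- mcfdti:::model_backward(params, fw$cache, dlogits, batch, cfg,
                                     plan)
    eps <- 1e-5
    walk <- function(path, p, g) {
      if (is.list(p)) {
        nms <- names(p)
        for (j in seq_along(p)) {
          gj <- if (!is.null(nms) && nzchar(nms[j])) g[[nms[j]]] else g[[j]]
          if (!is.null(gj)) walk(c(path, j), p[[j]], gj)
        }
      } else {
        for (i in sample(length(p), min(2L, length(p)))) {
          num <- (lossfn(set_in(params, path, i, eps)) -
                  lossfn(set_in(params, path, i, -eps))) / (2 * eps)
          expect_equal(g[i], num, tolerance = 1e-4,
                       info = paste(variant, paste(path, collapse = "/"), i))
        }
      }
    }
    set.seed(7)
    walk(integer(0), params, grads)
  }
})

test_that("zero-epoch training returns the untouched initialization", {
  recs <- tiny_records(24)
  cfg <- tiny_model_config()
  fit <- mcf_dti(recs, cfg, train_config(epochs = 0L, seed = 3L,
                                         batch_size = 8L))
  expect_length(fit$loss_history, 0L)
  ref <- mcfdti:::init_params(cfg, fit$plan, fit$vocab_smiles$size,
                              amino_acid_vocabulary()$size,
                              fit$bpe$vocab$size, 3L)
  expect_identical(fit$params, ref)
})

test_that("training reduces the loss on a learnable toy problem", {
  recs <- tiny_records(48, seed = 29L)
  fit <- mcf_dti(recs, tiny_model_config(),
                 train_config(epochs = 10L, seed = 11L, batch_size = 16L,
                              learning_rate = 0.003))
  h <- fit$loss_history
  expect_length(h, 10L)
  expect_lt(h[10], h[1])
  expect_true(all(is.finite(h)))
})

test_that("training is bit-reproducible under one seed", {
  recs <- tiny_records(24)
  cfg <- tiny_model_config(dropout = 0.2)   # dropout also seeded
  tc <- train_config(epochs = 3L, seed = 21L, batch_size = 8L)
  f1 <- mcf_dti(recs, cfg, tc)
  f2 <- mcf_dti(recs, cfg, tc)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$fitted, f2$fitted)
})

test_that("prediction is deterministic in evaluation mode", {
  recs <- tiny_records(24)
  fit <- mcf_dti(recs, tiny_model_config(dropout = 0.3),
                 train_config(epochs = 1L, seed = 2L, batch_size = 8L))
  p1 <- predict(fit, recs)
  p2 <- predict(fit, recs)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  cls <- predict(fit, recs, type = "class")
  expect_true(all(cls %in% c(0L, 1L)))
})

test_that("every architecture variant trains and predicts", {
  recs <- tiny_records(24)
  for (v in c("mscnn_mscnn", "mscnn_transformer", "mscnn2_mscnn2",
              "mscnn2_mscnn_transformer_s", "cnn_transformer",
              "mscnn_mscnn_transformer_c")) {
    fit <- mcf_dti(recs, tiny_model_config(),
                   train_config(epochs = 1L, seed = 4L, batch_size = 8L,
                                architecture_variant = v))
    p <- predict(fit, recs[1:5, ])
    expect_true(all(p >= 0 & p <= 1), info = v)
  }
})

test_that("held-out records never influence a fold's parameters", {
  recs <- tiny_records(32)
  fold <- stratified_kfold(recs$label, 2L, seed = 9L)
  tr_idx <- which(fold != 1L)
  cfg <- tiny_model_config()
  tc <- train_config(epochs = 1L, seed = 13L, batch_size = 8L)
  f1 <- mcf_dti(recs[tr_idx, ], cfg, tc)
  mutated <- recs
  mutated$smiles[which(fold == 1L)[1]] <- "NNNNNN"   # a held-out record
  f2 <- mcf_dti(mutated[tr_idx, ], cfg, tc)
  expect_identical(f1$params, f2$params)
})

test_that("cross-validation reports per-fold and mean metrics", {
  recs <- tiny_records(40)
  tc <- train_config(epochs = 1L, seed = 5L, batch_size = 16L, folds = 2L)
  rep1 <- crossval_evaluate(recs, tiny_model_config(), tc)
  expect_s3_class(rep1, "dti_eval_report")
  expect_equal(nrow(rep1$per_fold), 2L)
  expect_equal(sum(rep1$per_fold$n_eval), 40L)
  expect_equal(unname(rep1$mean["auc"]), mean(rep1$per_fold$auc))
  expect_true(all(unlist(rep1$per_fold[-1]) >= 0 &
                  unlist(rep1$per_fold[-1]) <= 40))

  rep2 <- crossval_evaluate(recs, tiny_model_config(), tc)
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_identical(rep1$mean, rep2$mean)

  ## pooled metrics use the out-of-fold predictions
  tcp <- tc; tcp$pooled_metrics <- TRUE
  rep3 <- crossval_evaluate(recs, tiny_model_config(), tcp)
  expect_equal(unname(rep3$mean["auc"]),
               auc_score(recs$label, rep3$oof_scores))
})

test_that("model objects support the standard S3 verbs", {
  recs <- tiny_records(24)
  fit <- mcf_dti(recs, tiny_model_config(),
                 train_config(epochs = 2L, seed = 6L, batch_size = 8L))
  expect_output(print(fit), "interaction model")
  s <- summary(fit)
  expect_gt(s$n_parameters, 100)
  expect_output(print(s), "training AUC")
  expect_equal(length(residuals(fit)), 24L)
  expect_type(coef(fit), "list")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("checkpoints round-trip and reject mismatched vocabularies", {
  recs <- tiny_records(24)
  fit <- mcf_dti(recs, tiny_model_config(),
                 train_config(epochs = 1L, seed = 8L, batch_size = 8L))
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_equal(predict(back, recs[1:6, ]), predict(fit, recs[1:6, ]),
               tolerance = 1e-10)

  ## tamper: checkpoint trained under a different vocabulary
  doc <- jsonlite::read_json(f, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  doc$vocab_tokens <- c(doc$vocab_tokens, "Z", "Q")
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f2, auto_unbox = FALSE, digits = NA)
  expect_error(load_checkpoint(f2), "incompatible")
})

test_that("training aborts with a diagnostic when the loss diverges", {
  recs <- tiny_records(24)
  expect_error(
    mcf_dti(recs, tiny_model_config(),
            train_config(epochs = 5L, seed = 1L, batch_size = 8L,
                         learning_rate = Inf)),
    "diverged|non-finite|learning rate")
})
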