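## Cross-validated training and evaluation.

fold_seed <- function(seed, fold) {
  as.integer((as.double(seed) * 131 + fold * 7919) %% 2147483647)
}

#' Cross-validated evaluation of the DTI classifier
#'
#' Stratified k-fold cross-validation: for each fold a model is trained
#' from scratch on the remaining folds (SMILES vocabulary and protein BPE
#' are rebuilt from the training fold only, so no information leaks from
#' held-out pairs) and evaluated on the held-out fold.  Headline metrics
#' are fold means by default; \code{pooled_metrics = TRUE} computes them
#' on the pooled out-of-fold predictions instead.
#'
#' @param records labelled records data.frame.
#' @param model_cfg a \code{\link{model_config}}.
#' @param train_cfg a \code{\link{train_config}} (its \code{folds} and
#'   \code{seed} drive the split).
#' @param verbose print per-fold progress.
#' @return An object of class \code{"dti_eval_report"}: list with
#'   \code{per_fold} (data.frame of AUC, AUPR, precision, recall,
#'   accuracy, n_eval per fold), \code{mean} (named numeric),
#'   \code{pooled} flag, \code{decision_threshold} and \code{n_eval}.
#' @export
crossval_evaluate <- function(records, model_cfg = model_config(),
                              train_cfg = train_config(), verbose = FALSE) {
  if (is.null(records$label)) stop2("records must carry a label column")
  k <- train_cfg$folds
  fold <- stratified_kfold(records$label, k, train_cfg$seed)
  rows <- vector("list", k)
  oof_scores <- numeric(nrow(records))
  for (i in seq_len(k)) {
    tr <- records[fold != i, , drop = FALSE]
    te <- records[fold == i, , drop = FALSE]
    tc <- train_cfg
    tc$seed <- fold_seed(train_cfg$seed, i)
    fit <- mcf_dti(tr, model_cfg, tc)
    sc <- predict(fit, te)
    oof_scores[fold == i] <- sc
    tm <- threshold_metrics(te$label, sc, train_cfg$decision_threshold)
    rows[[i]] <- data.frame(fold = i, n_eval = nrow(te),
                            auc = auc_score(te$label, sc),
                            aupr = aupr_score(te$label, sc),
                            precision = tm$precision, recall = tm$recall,
                            accuracy = tm$accuracy)
    if (verbose)
      message(sprintf("fold %d/%d: AUC %.4f AUPR %.4f", i, k,
                      rows[[i]]$auc, rows[[i]]$aupr))
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("auc", "aupr", "precision", "recall", "accuracy")
  means <- if (train_cfg$pooled_metrics) {
    tm <- threshold_metrics(records$label, oof_scores,
                            train_cfg$decision_threshold)
    c(auc = auc_score(records$label, oof_scores),
      aupr = aupr_score(records$label, oof_scores),
      precision = tm$precision, recall = tm$recall, accuracy = tm$accuracy)
  } else colMeans(per_fold[metric_cols])
  structure(list(per_fold = per_fold, mean = means,
                 pooled = train_cfg$pooled_metrics,
                 decision_threshold = train_cfg$decision_threshold,
                 n_eval = nrow(records), oof_scores = oof_scores,
                 fold = fold),
            class = "dti_eval_report")
}

#' @export
print.dti_eval_report <- function(x, digits = 4, ...) {
  cat("Cross-validated DTI evaluation (", nrow(x$per_fold), " folds, ",
      x$n_eval, " pairs)\n", sep = "")
  print(format(x$per_fold, digits = digits), row.names = FALSE)
  cat(if (x$pooled) "pooled:" else "mean:  ", " ",
      paste(names(x$mean), round(x$mean, digits), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an evaluation report as JSON
#'
#' @param report a \code{"dti_eval_report"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(per_fold = report$per_fold,
                            mean = as.list(report$mean),
                            pooled = report$pooled,
                            decision_threshold = report$decision_threshold,
                            n_eval = report$n_eval),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
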