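## Ranking and threshold metrics for binary classifiers.
##
## auc_score is the Mann-Whitney statistic (ties count 1/2); aupr_score is
## ranked average precision with tie-grouped precision: every positive in a
## group of tied scores receives the precision at the end of its group, so
## the value does not depend on the arbitrary order within ties.

check_labels_scores <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop2("labels and scores must have the same length")
  if (anyNA(labels) || anyNA(scores) || any(!is.finite(scores)))
    stop2("labels and scores must be finite and non-missing")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop2("labels must be binary 0/1")
  labels
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs in which the positive is scored higher, ties
#' counting one half.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric vector of classifier scores, same length.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(c(1, 1, 0, 0), c(0.9, 0.2, 0.5, 0.1))  # 0.75
#' @export
auc_score <- function(labels, scores) {
  labels <- check_labels_scores(labels, scores)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop2("AUC needs both classes present (got ", n1, " positives, ",
          n0, " negatives)")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Sum over ranked positives of precision at that rank times the recall
#' increment, with tie-grouped precision: all examples sharing a score are
#' treated as one rank group and each positive in the group receives the
#' precision at the end of the group.
#'
#' @inheritParams auc_score
#' @return AUPR in (0, 1\].
#' @examples
#' aupr_score(c(0, 1), c(0.9, 0.1))  # 0.5
#' @export
aupr_score <- function(labels, scores) {
  labels <- check_labels_scores(labels, scores)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop2("AUPR needs at least one positive label")
  ord <- order(-scores)
  lab <- labels[ord]; sc <- scores[ord]
  cum_tp <- cumsum(lab)
  rank_k <- seq_along(lab)
  ## end-of-group index for every position (groups of equal score)
  grp <- cumsum(!duplicated(sc))
  grp_end <- rank_k[!duplicated(sc, fromLast = TRUE)]
  end_of <- grp_end[grp]
  prec_at <- cum_tp[end_of] / end_of
  sum(prec_at[lab == 1L]) / n1
}

#' Confusion-matrix metrics at a decision threshold
#'
#' Scores at or above the threshold are predicted positive.  When nothing
#' is predicted positive, precision is undefined; it is reported as 0 with
#' \code{precision_defined = FALSE}.
#'
#' @inheritParams auc_score
#' @param threshold decision threshold on the score (default 0.5).
#' @return list with \code{accuracy}, \code{precision}, \code{recall} and
#'   \code{precision_defined}.
#' @export
threshold_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- check_labels_scores(labels, scores)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  npos_pred <- tp + fp
  list(accuracy = (tp + tn) / length(labels),
       precision = if (npos_pred > 0L) tp / npos_pred else 0,
       recall = if (tp + fn > 0L) tp / (tp + fn) else 0,
       precision_defined = npos_pred > 0L)
}

#' Stratified k-fold assignment
#'
#' Assigns each observation to one of \code{k} folds so that per-class
#' counts across folds differ by at most one; deterministic for a given
#' seed.
#'
#' @param labels binary 0/1 vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in \code{1..k}.
#' @export
stratified_kfold <- function(labels, k, seed) {
  labels <- as.integer(labels)
  if (!is_count(k, min = 2L)) stop2("k must be an integer >= 2")
  fold <- integer(length(labels))
  with_seed(derive_seed(seed, "folds"), {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      if (length(idx) < k)
        stop2("class ", cls, " has ", length(idx),
              " members, fewer than k = ", k)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
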