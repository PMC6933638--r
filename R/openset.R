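#' Maximum-softmax confidence scores
#'
#' The open-set score of a sequence is the maximum of its softmax vector:
#' in-distribution sequences tend to put most probability on one trained
#' family, while out-of-distribution sequences (other ncRNAs, unseen
#' families) spread it more evenly and score lower.
#'
#' @param classifier A `trained_classifier`.
#' @param encoded An `encoded_dataset` encoded as in training.
#' @return A data frame with columns `seq_id`, `class` (argmax family name),
#'   `max_prob`.
#' @export
max_softmax_scores <- function(classifier, encoded) {
  S <- predict_softmax(classifier, encoded)
  fam <- colnames(S)
  pred <- argmax_class(S)
  data.frame(seq_id = encoded$ids, class = fam[pred + 1L],
             max_prob = apply(S, 1, max), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' ROC curve for the accept/reject decision
#'
#' Positives are in-distribution sequences; accepting (score >= threshold)
#' is the positive decision. The curve sweeps every distinct score as a
#' threshold, plus sentinels giving the (0,0) and (1,1) endpoints, and the
#' AUC is computed by the trapezoid rule (equivalent to the Mann-Whitney
#' statistic with ties counted 1/2).
#'
#' @param pos_scores Scores of in-distribution sequences.
#' @param neg_scores Scores of out-of-distribution sequences.
#' @return A `roc_curve`: list with descending `thresholds`, `fpr`, `tpr`,
#'   `auc`, and the sample counts `n_pos`, `n_neg`.
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores)) {
    stop("both score sets must be non-empty")
  }
  thr <- c(Inf, sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE),
           -Inf)
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = length(pos_scores), n_neg = length(neg_scores)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC %.4f over %d positives / %d negatives\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Choose a rejection threshold from a ROC curve
#'
#' Two criteria are supported. `target_fpr`: the largest threshold (most
#' conservative accept rule) whose FPR is <= the target; if only the
#' degenerate reject-all threshold qualifies, that sentinel is returned with
#' a warning. `max_fscore`: the threshold maximizing the F-score of the
#' accept decision (precision over accepted sequences, recall over
#' positives), ties resolved toward the larger threshold.
#'
#' @param curve A `roc_curve`.
#' @param target_fpr Target false-positive rate (e.g. 0.05), or `NULL`.
#' @param max_fscore Set `TRUE` to use the F-score criterion instead.
#' @return A single threshold value.
#' @export
choose_threshold <- function(curve, target_fpr = NULL, max_fscore = FALSE) {
  thr <- curve$thresholds
  if (isTRUE(max_fscore)) {
    tp <- curve$tpr * curve$n_pos
    fp <- curve$fpr * curve$n_neg
    fn <- curve$n_pos - tp
    precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    fs <- ifelse(precision + recall > 0,
                 2 * precision * recall / (precision + recall), 0)
    return(thr[which.max(fs)])  # first index = largest threshold on ties
  }
  if (is.null(target_fpr)) stop("give target_fpr or max_fscore = TRUE")
  ok <- which(curve$fpr <= target_fpr)
  best <- max(ok)  # smallest qualifying threshold (thresholds descend)
  if (is.infinite(thr[best]) && best == 1L) {
    warning("only the degenerate reject-all threshold meets the FPR target")
    return(max(c(curve$thresholds[is.finite(curve$thresholds)], 1)) + 1)
  }
  thr[best]
}

#' Classify with open-set rejection
#'
#' Sequences whose maximum softmax probability falls below `threshold` are
#' assigned the reserved class `"rejected"`; a score equal to the threshold
#' is accepted.
#'
#' @param classifier A `trained_classifier`.
#' @param encoded An `encoded_dataset` encoded as in training.
#' @param threshold Rejection threshold in [0, 1]; defaults to the
#'   classifier's stored threshold (0.977 unless recalibrated).
#' @return A data frame with `seq_id`, `class` (family or `"rejected"`),
#'   `max_prob`, `accepted`.
#' @export
predict_with_rejection <- function(classifier, encoded,
                                   threshold = classifier$threshold) {
  stopifnot(threshold >= 0 || threshold <= 1)
  scores <- max_softmax_scores(classifier, encoded)
  scores$accepted <- scores$max_prob >= threshold
  scores$class[!scores$accepted] <- "rejected"
  scores
}

#' Write scores / ROC tables as TSV
#'
#' `write_scores_tsv` writes `<seq_id> <predicted_family> <max_prob>
#' <accepted>`; `write_roc_tsv` writes `<threshold> <fpr> <tpr>`.
#'
#' @param x A scored-prediction data frame or a `roc_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(x, path) {
  utils::write.table(x[, c("seq_id", "class", "max_prob", "accepted")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
write_roc_tsv <- function(x, path) {
  utils::write.table(
    data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
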