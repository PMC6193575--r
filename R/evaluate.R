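# Threshold-dependent metrics (Ac, Sp, Sn, MCC), ROC/AUC, and the
# cross-validated report.

#' Confusion counts at a cutoff
#'
#' A score at or above the cutoff is a positive call.
#'
#' @param scores Numeric prediction scores.
#' @param labels "positive"/"negative" per score.
#' @param cutoff Decision threshold.
#' @return List of class `confusion`: nTP, nTN, nFP, nFN.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  stopifnot(length(scores) == length(labels), length(scores) > 0L)
  call_pos <- scores >= cutoff
  is_pos <- labels == "positive"
  structure(list(nTP = sum(call_pos & is_pos),
                 nTN = sum(!call_pos & !is_pos),
                 nFP = sum(call_pos & !is_pos),
                 nFN = sum(!call_pos & is_pos),
                 cutoff = cutoff),
            class = "confusion")
}

#' Accuracy, specificity, sensitivity and MCC from confusion counts
#'
#' Ac = (nTP + nTN) / total; Sp = nTN / (nTN + nFP);
#' Sn = nTP / (nTP + nFN);
#' MCC = (nTP nTN - nFP nFN) / sqrt((nTN+nFN)(nTP+nFP)(nTP+nFN)(nTN+nFP)).
#' Any metric whose denominator is zero is reported as 0.
#'
#' @param counts A `confusion` object or list with nTP/nTN/nFP/nFN.
#' @return List of class `metric_report`: Ac, Sp, Sn, MCC, cutoff.
#' @export
metrics <- function(counts) {
  tp <- counts$nTP; tn <- counts$nTN; fp <- counts$nFP; fn <- counts$nFN
  total <- tp + tn + fp + fn
  if (total == 0L) stop("empty confusion table")
  safe <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(as.numeric(tn + fn) * (tp + fp) * (tp + fn) * (tn + fp))
  structure(list(Ac = (tp + tn) / total,
                 Sp = safe(tn, tn + fp),
                 Sn = safe(tp, tp + fn),
                 MCC = if (mcc_den == 0) 0 else
                   (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den,
                 cutoff = counts$cutoff),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Ac = %.4f  Sp = %.4f  Sn = %.4f  MCC = %.4f (cutoff %s)\n",
              x$Ac, x$Sp, x$Sn, x$MCC,
              if (is.null(x$cutoff)) "?" else format(x$cutoff)))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (tied scores step
#' simultaneously) and integrates the curve by the trapezoid rule, which
#' equals the Mann-Whitney concordance probability.
#'
#' @param scores Numeric prediction scores.
#' @param labels "positive"/"negative" per score; both classes required.
#' @return List of class `roc_curve`: `points` (data.frame fpr, tpr,
#'   starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  is_pos <- labels == "positive"
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0L || nn == 0L) stop("both classes required for a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- is_pos[o]
  # step once per distinct score value
  last <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(y)[last] / np)
  fpr <- c(0, cumsum(!y)[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC:", nrow(x$points), "points, AUC =", signif(x$auc, 4), "\n")
  invisible(x)
}

#' Stratified 10-fold cross-validated performance report
#'
#' For each fold the entire training workflow is repeated on the other
#' folds — feature selection, the five channels and the score fusion — and
#' the held-out fold is scored, so the report is free of selection and
#' fusion leakage. Within each training fold the fusion is fitted on
#' out-of-bag channel votes (`fusion_scores = "oob"`, the default here,
#' avoids a second nested fold loop; `"oof"` nests one).
#'
#' @param features Labelled `gpsuc_features` matrix.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @param top_n,num_trees,fix_alpha_zero,cutoff_mode,cutoff_target,cutoff_value
#'   As in [train_model()].
#' @param fusion_scores "oob" (default) or "oof".
#' @param inner_folds Folds of the nested loop when `fusion_scores = "oof"`.
#' @return List of class `cv_report`: `per_fold` (data.frame of fold
#'   metrics + AUC), `mean` (averages), `fold` (assignment), `scores`
#'   (held-out fused probability per window).
#' @export
cross_validated_report <- function(features, folds = 10, seed = 1,
                                   top_n = c(pCKSAAP = 390, AAindex = 250),
                                   num_trees = 500,
                                   fix_alpha_zero = TRUE,
                                   fusion_scores = c("oob", "oof"),
                                   inner_folds = 5,
                                   cutoff_mode = "specificity",
                                   cutoff_target = 0.90,
                                   cutoff_value = 0.5) {
  fusion_scores <- match.arg(fusion_scores)
  labels <- attr(features, "meta")$label
  fold <- make_folds(labels, folds, seed)
  oof_p <- rep(NA_real_, nrow(features))
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    tr_feat <- features_subset(features, seq_len(ncol(features)), tr)
    model <- train_model(tr_feat, top_n = top_n, num_trees = num_trees,
                         folds = inner_folds, seed = seed + f,
                         fix_alpha_zero = fix_alpha_zero,
                         fusion_scores = fusion_scores,
                         cutoff_mode = cutoff_mode,
                         cutoff_target = cutoff_target,
                         cutoff_value = cutoff_value)
    te_feat <- features_subset(features, seq_len(ncol(features)), te)
    sc <- matrix(NA_real_, nrow = length(te), ncol = 5L,
                 dimnames = list(NULL, CHANNEL_ORDER))
    for (enc in CHANNEL_ORDER)
      sc[, enc] <- score_channel(model$channels[[enc]], te_feat)
    p <- fusion_predict(model$fusion, sc)
    oof_p[te] <- p
    m <- metrics(confusion_at_cutoff(p, labels[te], model$fusion$cutoff))
    rows[[f]] <- data.frame(fold = f, Ac = m$Ac, Sp = m$Sp, Sn = m$Sn,
                            MCC = m$MCC, auc = roc_auc(p, labels[te])$auc,
                            cutoff = model$fusion$cutoff)
  }
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[, c("Ac", "Sp", "Sn", "MCC",
                                              "auc")]),
                 fold = fold, scores = oof_p),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(nrow(x$per_fold), "-fold cross-validation (means):\n", sep = "")
  print(round(x$mean, 4))
  invisible(x)
}
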