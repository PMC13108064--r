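# Confusion-matrix metrics (one-vs-rest reductions of the 3x3 matrix),
# extended multiclass agreement metrics, one-vs-rest ROC/AUC, and
# normalized confusion matrices.

metric_or_na <- function(num, den, reason) {
  if (den == 0) {
    out <- NA_real_
    attr(out, "reason") <- reason
    out
  } else num / den
}

#' Confusion counts and per-class / global performance metrics
#'
#' Reduces the multiclass confusion matrix one-vs-rest per class and
#' computes sensitivity (Se = TP/(TP+FN)), specificity (Sp = TN/(TN+FP)),
#' PPV, NPV, FPR = FP/(FP+TN), FNR = FN/(TP+FN), F1 and accuracy, plus
#' global accuracy and macro/weighted F1. Ratios with zero denominators
#' are reported as `NA` (never silently 0 or 1) with a reason code in
#' `reasons`.
#'
#' @param truth,predicted equal-length label vectors over the same class
#'   set.
#' @param levels class levels (default the three study groups).
#' @return list: `confusion` (K x K matrix, rows = truth), `counts`
#'   (per-class TP/TN/FP/FN), `per_class` (data.frame of metrics),
#'   `accuracy`, `macro_f1`, `weighted_f1`, `normalized_confusion` (rows
#'   sum to 1), `reasons`.
#' @export
confusion_and_metrics <- function(truth, predicted, levels = CLASS_LEVELS) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted) || length(truth) == 0)
    stop("label vectors must be equal-length and non-empty")
  if (!all(c(truth, predicted) %in% levels))
    stop("label outside the declared class set")
  tf <- factor(truth, levels = levels)
  pf <- factor(predicted, levels = levels)
  cm <- table(truth = tf, predicted = pf)
  n <- length(truth)
  reasons <- character(0)
  rows <- lapply(levels, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    se <- metric_or_na(tp, tp + fn, "no positives in truth")
    sp <- metric_or_na(tn, tn + fp, "no negatives in truth")
    ppv <- metric_or_na(tp, tp + fp, "class never predicted")
    npv <- metric_or_na(tn, tn + fn, "rest never predicted")
    f1 <- if (is.na(se) || is.na(ppv) || se + ppv == 0) NA_real_ else
      2 * se * ppv / (se + ppv)
    for (m in c("se", "sp", "ppv", "npv")) {
      v <- get(m)
      if (is.na(v)) reasons[paste0(cl, ":", m)] <<- attr(v, "reason")
    }
    data.frame(class = cl, tp = tp, tn = tn, fp = fp, fn = fn,
               sensitivity = as.numeric(se), specificity = as.numeric(sp),
               ppv = as.numeric(ppv), npv = as.numeric(npv),
               fpr = 1 - as.numeric(sp), fnr = 1 - as.numeric(se),
               f1 = f1, accuracy = (tp + tn) / n)
  })
  per_class <- do.call(rbind, rows)
  support <- as.numeric(table(tf))
  macro_f1 <- mean(per_class$f1)
  weighted_f1 <- sum(per_class$f1 * support, na.rm = FALSE) / sum(support)
  norm_cm <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
  list(confusion = unclass(cm),
       counts = per_class[, c("class", "tp", "tn", "fp", "fn")],
       per_class = per_class,
       accuracy = sum(diag(cm)) / n,
       macro_f1 = macro_f1, weighted_f1 = weighted_f1,
       normalized_confusion = unclass(norm_cm),
       reasons = reasons)
}

# rank-statistic AUC for one class vs rest (Mann-Whitney with tie handling)
auc_rank <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores); n0 <- length(neg_scores)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest ROC curves and AUC
#'
#' Per-class AUC via the rank (Mann-Whitney) statistic of the class scores
#' against the rest; macro AUC is the unweighted mean over classes present
#' in the truth, micro AUC pools all (sample, class) indicator pairs. ROC
#' curve points are returned for plotting.
#'
#' @param truth label vector.
#' @param scores n x K score matrix with class columns.
#' @param levels class levels.
#' @return list: `per_class` (named AUCs, `NA` for absent classes),
#'   `macro`, `micro`, `curves` (data.frame class/fpr/tpr).
#' @export
ovr_roc_auc <- function(truth, scores, levels = CLASS_LEVELS) {
  if (!all(is.finite(scores))) stop("score matrix must be finite")
  truth <- as.character(truth)
  if (is.null(colnames(scores))) colnames(scores) <- levels
  per_class <- stats::setNames(rep(NA_real_, length(levels)), levels)
  curves <- NULL
  for (cl in levels) {
    pos <- truth == cl
    if (!any(pos)) next
    per_class[cl] <- auc_rank(scores[pos, cl], scores[!pos, cl])
    th <- sort(unique(scores[, cl]), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(scores[pos, cl] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(scores[!pos, cl] >= t), numeric(1))
    curves <- rbind(curves,
                    data.frame(class = cl, threshold = c(Inf, th, -Inf),
                               fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
  }
  ind <- as.vector(vapply(levels, function(cl) as.numeric(truth == cl),
                          numeric(length(truth))))
  micro <- auc_rank(as.vector(scores[, levels])[ind == 1],
                    as.vector(scores[, levels])[ind == 0])
  list(per_class = per_class, macro = mean(per_class, na.rm = TRUE),
       micro = micro, curves = curves)
}

#' Cohen's kappa, multiclass MCC and balanced accuracy
#'
#' Kappa compares observed with chance agreement from the marginals; MCC
#' is the multiclass generalization computed from the full confusion
#' matrix; balanced accuracy is the mean per-class recall.
#'
#' @inheritParams confusion_and_metrics
#' @return list `kappa`, `mcc`, `balanced_accuracy` (`kappa` is `NA` for
#'   degenerate single-class truth).
#' @export
agreement_metrics <- function(truth, predicted, levels = CLASS_LEVELS) {
  cm <- table(factor(as.character(truth), levels = levels),
              factor(as.character(predicted), levels = levels))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (length(unique(as.character(truth))) < 2 || pe == 1) NA_real_
           else (po - pe) / (1 - pe)
  tk <- rowSums(cm); pk <- colSums(cm)
  cov_tp <- n * sum(diag(cm)) - sum(tk * pk)
  den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  mcc <- if (den == 0) NA_real_ else cov_tp / den
  recalls <- diag(cm) / tk
  list(kappa = kappa, mcc = mcc,
       balanced_accuracy = mean(recalls[tk > 0]))
}

#' Full performance report
#'
#' Combines [confusion_and_metrics()], [agreement_metrics()] and, when a
#' score matrix is supplied, [ovr_roc_auc()].
#'
#' @inheritParams confusion_and_metrics
#' @param scores optional n x 3 score matrix.
#' @return list of class `PerformanceReport`.
#' @export
performance_report <- function(truth, predicted, scores = NULL,
                               levels = CLASS_LEVELS) {
  rep <- confusion_and_metrics(truth, predicted, levels)
  rep <- c(rep, agreement_metrics(truth, predicted, levels))
  if (!is.null(scores)) rep$auc <- ovr_roc_auc(truth, scores, levels)
  class(rep) <- "PerformanceReport"
  rep
}

#' @export
print.PerformanceReport <- function(x, ...) {
  cat(sprintf("Accuracy %.3f | macro F1 %.3f | balanced acc %.3f | kappa %.3f | MCC %.3f",
              x$accuracy, x$macro_f1, x$balanced_accuracy, x$kappa, x$mcc))
  if (!is.null(x$auc)) cat(sprintf(" | macro AUC %.3f", x$auc$macro))
  cat("\n")
  invisible(x)
}
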