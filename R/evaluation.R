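#' Confusion counts for the binary HC/OA problem
#'
#' OA (disease) is the positive class: `tp` counts OA cases called OA,
#' `tn` HC cases called HC.
#'
#' @param labels true labels (`"HC"`/`"OA"`).
#' @param predictions predicted labels, same length.
#' @return object of class `vag_confusion`: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predictions) {
  labels <- as.character(labels); predictions <- as.character(predictions)
  if (length(labels) != length(predictions)) stop("length mismatch")
  bad <- setdiff(unique(c(labels, predictions)), c("HC", "OA"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  structure(list(tp = sum(labels == "OA" & predictions == "OA"),
                 fp = sum(labels == "HC" & predictions == "OA"),
                 tn = sum(labels == "HC" & predictions == "HC"),
                 fn = sum(labels == "OA" & predictions == "HC")),
            class = "vag_confusion")
}

#' Construct confusion counts directly
#' @param tp,fp,tn,fn non-negative integer counts (OA positive).
#' @return a `vag_confusion`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn), class = "vag_confusion")
}

#' Derived classification metrics from confusion counts
#'
#' Standard definitions with OA positive: accuracy (as a percentage),
#' sensitivity = recall = tp/(tp+fn), specificity = tn/(tn+fp),
#' precision = tp/(tp+fp), F1 = harmonic mean of precision and recall, and
#' the Matthews correlation coefficient. Per-class correct counts and
#' percentages are reported in the layout of the reference study's summary
#' tables. Because published reports sometimes swap the sensitivity/precision
#' orientation, the class-swapped pair is also included
#' (`sensitivity_swapped` = specificity-like value obtained with HC treated
#' as positive, etc.); F1 and MCC are orientation-stable anchors.
#' Metrics with a zero denominator are returned as `NA` and listed in
#' `undefined`.
#'
#' @param counts a `vag_confusion`.
#' @return list of metrics.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "vag_confusion"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  undefined <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); return(NA_real_) }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    undefined <- c(undefined, "f1"); NA_real_
  } else 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { undefined <- c(undefined, "mcc"); NA_real_ }
         else (tp * tn - fp * fn) / mcc_den
  list(counts = list(tp = tp, fp = fp, tn = tn, fn = fn), total = total,
       hc_total = tn + fp, hc_correct = tn,
       hc_correct_pct = safe(100 * tn, tn + fp, "hc_correct_pct"),
       oa_total = tp + fn, oa_correct = tp,
       oa_correct_pct = safe(100 * tp, tp + fn, "oa_correct_pct"),
       accuracy_pct = 100 * (tp + tn) / total,
       sensitivity = sens, specificity = spec,
       precision = prec, recall = sens, f1 = f1, mcc = mcc,
       sensitivity_swapped = spec, precision_swapped = safe(tn, tn + fn,
                                                            "precision_swapped"),
       undefined = undefined)
}

#' ROC points from OA probabilities
#'
#' Sweeps the decision threshold over the unique scores (classifying as OA
#' when `score >= threshold`) and returns the operating points, anchored at
#' (0, 0) (threshold above every score) and (1, 1) (threshold `-Inf`).
#'
#' @param scores OA-class probabilities or scores.
#' @param labels true labels (`"HC"`/`"OA"`); both classes must be present.
#' @return data.frame with columns `fpr`, `tpr`, `threshold`, ordered by
#'   increasing false-positive rate.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to build a ROC curve")
  pos <- labels == "OA"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & !pos) / n_neg, tpr = sum(pred & pos) / n_pos)
  }, c(fpr = 0, tpr = 0)))
  out <- data.frame(fpr = pts[, 1], tpr = pts[, 2], threshold = thr)
  out[order(out$fpr, out$tpr), ]
}

#' Area under the ROC curve (trapezoidal)
#' @param roc a [roc_points()] data.frame.
#' @return scalar in [0, 1].
#' @export
roc_auc <- function(roc) {
  stopifnot(all(c("fpr", "tpr") %in% names(roc)))
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Operating threshold of a ROC curve
#'
#' The cutoff maximizing Youden's J = sensitivity + specificity - 1, with
#' ties broken toward the larger threshold.
#'
#' @param roc a [roc_points()] data.frame.
#' @return scalar threshold.
#' @export
operating_threshold <- function(roc) {
  j <- roc$tpr - roc$fpr
  finite <- is.finite(roc$threshold)
  cand <- which(j == max(j[finite]) & finite)
  max(roc$threshold[cand])
}

#' Assemble a full evaluation report
#'
#' Confusion counts at the argmax decision rule, every derived metric, the
#' ROC point list, its AUC, and the Youden-optimal operating threshold.
#'
#' @param labels true labels.
#' @param scores OA-class probabilities.
#' @param predictions optional predicted labels; default `"OA"` when
#'   `score >= 0.5`.
#' @return list of class `vag_report`.
#' @export
evaluation_report <- function(labels, scores, predictions = NULL) {
  labels <- as.character(labels)
  if (is.null(predictions)) predictions <- ifelse(scores >= 0.5, "OA", "HC")
  m <- confusion_metrics(confusion(labels, predictions))
  roc <- roc_points(scores, labels)
  m$roc <- data.frame(fpr = roc$fpr, tpr = roc$tpr,
                      threshold = ifelse(is.finite(roc$threshold),
                                         roc$threshold, NA_real_))
  m$auc <- roc_auc(roc)
  m$roc_threshold <- operating_threshold(roc)
  class(m) <- c("vag_report", "list")
  m
}

#' @export
print.vag_report <- function(x, ...) {
  cat(sprintf("<vag_report> acc=%.2f%% sens=%.3f spec=%.3f F1=%.3f MCC=%.3f AUC=%.3f\n",
              x$accuracy_pct, x$sensitivity, x$specificity, x$f1, x$mcc, x$auc))
  invisible(x)
}
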