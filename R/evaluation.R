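#' Confusion counts for a binary classifier
#'
#' Tabulates true/false positives and negatives, treating the "active"
#' (BBB-permeating) class as positive.
#'
#' @param y_true true labels; 0/1, logical, or "active"/"inactive".
#' @param y_pred predicted labels, same encodings accepted.
#' @return object of class `bbb_confusion`: list with integer fields
#'   `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(y_true, y_pred) {
  assert_that(length(y_true) == length(y_pred),
              "y_true and y_pred must have equal length")
  assert_that(length(y_true) > 0, "empty input")
  t_act <- is_active(y_true)
  p_act <- is_active(y_pred)
  assert_that(!anyNA(t_act) && !anyNA(p_act), "labels must be binary, no NA")
  out <- list(tp = sum(t_act & p_act), fn = sum(t_act & !p_act),
              fp = sum(!t_act & p_act), tn = sum(!t_act & !p_act))
  out <- lapply(out, as.integer)
  structure(out, class = "bbb_confusion")
}

#' Build confusion counts directly
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return `bbb_confusion` object.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  assert_that(all(v >= 0) && all(v == round(v)), "counts must be non-negative integers")
  structure(as.list(as.integer(v)) |> stats::setNames(names(v)),
            class = "bbb_confusion")
}

metric_undefined <- function(reason) {
  structure(NA_real_, undefined = reason)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) metric_undefined(paste0(what, ": zero denominator")) else num / den
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity (recall), specificity, accuracy, balanced accuracy,
#' precision, F1 (harmonic mean of precision and recall), the Matthews
#' correlation coefficient and Cohen's kappa (chance agreement
#' \eqn{P_e = [(TP+FN)(TP+FP) + (FP+TN)(FN+TN)]/n^2}).  A metric whose
#' defining ratio has a zero denominator (e.g. MCC with an empty confusion
#' row or column) is reported as `NA` carrying an `undefined` attribute
#' naming the zero margin, never silently as 0.
#'
#' @param counts a `bbb_confusion` object (see [confusion()]).
#' @param roc_auc optional precomputed ROC-AUC to attach to the report.
#' @return object of class `bbb_metrics`: named list of metric values plus
#'   the `counts`.
#' @export
metrics <- function(counts, roc_auc = NULL) {
  stopifnot(inherits(counts, "bbb_confusion"))
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  n <- tp + fn + fp + tn
  assert_that(n > 0, "empty confusion matrix")

  sens <- safe_ratio(tp, tp + fn, "sensitivity (no positives)")
  spec <- safe_ratio(tn, tn + fp, "specificity (no negatives)")
  acc  <- (tp + tn) / n
  bacc <- if (is.na(sens) || is.na(spec))
    metric_undefined("balanced accuracy: a class is absent") else (sens + spec) / 2
  prec <- safe_ratio(tp, tp + fp, "precision (no positive predictions)")
  f1 <- if (is.na(prec) || is.na(sens))
    metric_undefined("F1: precision or recall undefined")
  else if (prec + sens == 0)
    metric_undefined("F1: precision and recall both zero")
  else 2 * prec * sens / (prec + sens)

  mcc_den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0)
    metric_undefined("MCC: a confusion-matrix row or column is zero")
  else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(mcc_den)

  pe <- (as.numeric(tp + fn) * (tp + fp) + as.numeric(fp + tn) * (fn + tn)) / n^2
  kappa <- if (pe == 1) metric_undefined("kappa: chance agreement is 1")
  else (acc - pe) / (1 - pe)

  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 balanced_accuracy = bacc, precision = prec, f1 = f1,
                 mcc = mcc, kappa = kappa,
                 roc_auc = roc_auc %||% NA_real_,
                 counts = counts),
            class = "bbb_metrics")
}

#' @export
print.bbb_metrics <- function(x, digits = 4, ...) {
  cat("BBB classification metrics (n =",
      with(x$counts, tp + fn + fp + tn), ")\n")
  cat(sprintf("  counts: TP=%d FN=%d FP=%d TN=%d\n",
              x$counts$tp, x$counts$fn, x$counts$fp, x$counts$tn))
  for (m in setdiff(names(x), "counts")) {
    v <- x[[m]]
    cat(sprintf("  %-18s %s\n", m,
                if (is.na(v)) paste0("undefined (", attr(v, "undefined") %||% "NA", ")")
                else format(round(v, digits), nsmall = digits)))
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Threshold-sweep ROC: predictions are sorted by decreasing positive-class
#' probability, the curve steps 1/#positives up or 1/#negatives right, and
#' tied scores are collapsed into single diagonal segments (trapezoidal
#' area), which makes the result identical to the rank-statistic
#' formulation \eqn{P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)}.
#'
#' @param y_true true binary labels.
#' @param probabilities positive-class scores, finite.
#' @return AUC in \[0,1\]; `NA` with an `undefined` attribute when only one
#'   class is present in `y_true`.
#' @export
roc_auc <- function(y_true, probabilities) {
  assert_that(length(y_true) == length(probabilities),
              "labels and probabilities must have equal length")
  assert_that(all(is.finite(probabilities)), "probabilities must be finite")
  pos <- is_active(y_true)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    return(metric_undefined("ROC-AUC: single-class truth"))
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]; y <- pos[ord]
  # collapse tied scores into blocks; within a block the curve is a diagonal
  blocks <- cumsum(!duplicated(p))
  tp_blk <- tapply(y, blocks, sum)
  fp_blk <- tapply(!y, blocks, sum)
  tpr <- cumsum(tp_blk) / n_pos
  fpr <- cumsum(fp_blk) / n_neg
  tpr0 <- c(0, tpr); fpr0 <- c(0, fpr)
  sum(diff(fpr0) * (utils::head(tpr0, -1) + utils::tail(tpr0, -1)) / 2)
}

#' Evaluate predictions against truth
#'
#' Convenience wrapper: confusion counts + full metric report, with ROC-AUC
#' when probabilities are supplied.
#'
#' @param y_true,y_pred binary label vectors.
#' @param probabilities optional positive-class probabilities for ROC-AUC.
#' @return `bbb_metrics` report.
#' @export
evaluate_predictions <- function(y_true, y_pred, probabilities = NULL) {
  auc <- if (!is.null(probabilities)) roc_auc(y_true, probabilities)
  metrics(confusion(y_true, y_pred), roc_auc = auc)
}
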