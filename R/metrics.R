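#' Confusion matrix for binary predictions
#'
#' @param truth,predicted equal-length vectors of class labels.
#' @param positive the label counted as positive.
#' @return object of class `grq_cm`: list with `tp`, `fn`, `tn`, `fp` and
#'   `positive`.
#' @export
confusion <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  if (length(truth) == 0) stop("empty inputs")
  t_pos <- truth == positive
  p_pos <- predicted == positive
  out <- list(tp = sum(t_pos & p_pos), fn = sum(t_pos & !p_pos),
              tn = sum(!t_pos & !p_pos), fp = sum(!t_pos & p_pos),
              positive = positive)
  class(out) <- "grq_cm"
  out
}

#' Build a confusion matrix from counts
#'
#' @param tp,fn,tn,fp non-negative integer cells.
#' @param positive positive class name (informational).
#' @return a `grq_cm`.
#' @export
confusion_from_counts <- function(tp, fn, tn, fp, positive = "positive") {
  if (any(c(tp, fn, tn, fp) < 0)) stop("cells must be non-negative")
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp, positive = positive),
            class = "grq_cm")
}

#' @export
print.grq_cm <- function(x, ...) {
  cat(sprintf("Confusion matrix (positive = %s): tp=%d fn=%d tn=%d fp=%d\n",
              x$positive, x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Threshold metrics from a confusion matrix
#'
#' Sensitivity `SN = tp / (tp + fn)`, specificity `SP = tn / (tn + fp)`,
#' balanced accuracy `BACC = (SN + SP) / 2`, `F1 = 2 tp / (2 tp + fp + fn)`
#' and the Matthews correlation coefficient
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' convention that MCC (and any rate with an empty denominator) is 0 when a
#' marginal count is zero.
#'
#' @param cm a `grq_cm`.
#' @return list with `sn`, `sp`, `bacc`, `mcc`, `f1`, `acc` and the `cm`.
#' @export
metrics_from_cm <- function(cm) {
  tp <- cm$tp; fn <- cm$fn; tn <- cm$tn; fp <- cm$fp
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  denom_factors <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(denom_factors == 0)) 0 else {
    (tp * tn - fp * fn) / sqrt(prod(denom_factors))
  }
  list(sn = sn, sp = sp, bacc = (sn + sp) / 2, mcc = mcc, f1 = f1,
       acc = safe_div(tp + tn, tp + fn + tn + fp), cm = cm)
}

#' Recover an integer confusion matrix from printed sensitivity/specificity
#'
#' Published tables often print SN and SP rounded to a few decimals together
#' with the per-class test sizes. Because the underlying cells are integers,
#' an exhaustive search over `tp` in `0..n_pos` and `tn` in `0..n_neg` for
#' cells whose rates round to the printed values recovers the confusion
#' matrix — uniquely, in the common case — and with it every derived metric
#' (BACC, MCC, F1) at full precision.
#'
#' @param sn,sp printed rates.
#' @param n_pos,n_neg per-class totals.
#' @param digits rounding precision of the printed rates (default 3).
#' @return the unique matching `grq_cm`, or a list of `grq_cm` when several
#'   cells round to the same rates (with a warning).
#' @export
recover_cm_from_rates <- function(sn, sp, n_pos, n_neg, digits = 3) {
  tp_hit <- which(round(0:n_pos / n_pos, digits) == round(sn, digits)) - 1L
  tn_hit <- which(round(0:n_neg / n_neg, digits) == round(sp, digits)) - 1L
  if (!length(tp_hit) || !length(tn_hit)) {
    stop(sprintf("no integer cells reproduce SN=%.3f / SP=%.3f with %d/%d totals (table inconsistency?)",
                 sn, sp, n_pos, n_neg))
  }
  cms <- list()
  for (tp in tp_hit) for (tn in tn_hit) {
    cms[[length(cms) + 1L]] <- confusion_from_counts(
      tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
  }
  if (length(cms) == 1) cms[[1]] else {
    warning(length(cms), " confusion matrices match; returning all")
    cms
  }
}

#' ROC and precision-recall curves with their areas
#'
#' AUC is computed by the trapezoidal rule over the ROC points of all score
#' thresholds; AUPR by step-wise summation `sum((R_i - R_{i-1}) * P_i)` over
#' the PR points in order of decreasing threshold. Tied scores are grouped so
#' that a tie never splits a threshold.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels class labels; both classes must be present.
#' @param positive the positive label.
#' @return list with `auc`, `aupr`, `roc` (data.frame fpr/tpr/threshold) and
#'   `pr` (data.frame recall/precision/threshold).
#' @export
roc_pr_curves <- function(scores, labels, positive) {
  if (length(scores) != length(labels)) stop("scores and labels must have equal length")
  y <- labels == positive
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")

  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # group ties: cumulative counts at the end of each tie group
  grp_end <- which(!duplicated(s, fromLast = TRUE))
  cum_tp <- cumsum(y)[grp_end]
  cum_fp <- cumsum(!y)[grp_end]
  thr <- s[grp_end]

  tpr <- c(0, cum_tp / n_pos)
  fpr <- c(0, cum_fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  recall <- cum_tp / n_pos
  precision <- ifelse(cum_tp + cum_fp == 0, 1, cum_tp / (cum_tp + cum_fp))
  aupr <- sum(diff(c(0, recall)) * precision)

  list(auc = auc, aupr = aupr,
       roc = data.frame(fpr = fpr[-1], tpr = tpr[-1], threshold = thr),
       pr = data.frame(recall = recall, precision = precision, threshold = thr))
}

#' Full metric report from scores
#'
#' Thresholds scores at 0.5 (configurable), computes the confusion matrix,
#' all threshold metrics and the ranking metrics.
#'
#' @inheritParams roc_pr_curves
#' @param threshold hard-label cutoff on the scores.
#' @param mode report tag, e.g. `"independent"` or `"cv_mean"`.
#' @return object of class `grq_metrics`.
#' @export
score_metrics <- function(scores, labels, positive, threshold = 0.5,
                          mode = "independent") {
  pred <- ifelse(scores >= threshold, positive, paste0("not_", positive))
  lab_bin <- ifelse(labels == positive, positive, paste0("not_", positive))
  cm <- confusion(lab_bin, pred, positive)
  th <- metrics_from_cm(cm)
  curves <- roc_pr_curves(scores, labels, positive)
  out <- c(th[c("sn", "sp", "bacc", "mcc", "f1", "acc")],
           list(auc = curves$auc, aupr = curves$aupr, cm = cm,
                positive = positive, mode = mode))
  class(out) <- "grq_metrics"
  out
}

#' @export
print.grq_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("Metrics (%s, positive = %s):\n", x$mode, x$positive))
  vals <- unlist(x[c("bacc", "sn", "sp", "mcc", "auc", "f1", "aupr")])
  print(round(vals, digits))
  invisible(x)
}

#' Collect metric reports into a table
#'
#' @param reports named list of `grq_metrics`.
#' @return data.frame with one row per report, columns matching the
#'   BACC/SN/SP/MCC/AUC/F1/AUPR layout of published comparison tables.
#' @export
metrics_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(method = nm, bacc = r$bacc, sn = r$sn, sp = r$sp, mcc = r$mcc,
               auc = r$auc %||% NA_real_, f1 = r$f1, aupr = r$aupr %||% NA_real_,
               mode = r$mode %||% NA_character_)
  }))
}
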